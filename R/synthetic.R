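## Seeded synthetic corpora exhibiting the segmentation phenomena the rule
## tokenizer is designed to repair. Surfaces are synthesized from fixed
## template vocabularies, not copied from annotated corpora.

.SYN <- list(
    fillers = c("the", "study", "shows", "that", "treatment", "with",
                "reduced", "levels", "in", "patients", "after", "exposure",
                "to", "measured", "samples", "during", "trial", "observed",
                "effect", "on", "cells", "was", "significant", "compared",
                "control", "group", "baseline", "values", "increased",
                "response"),
    stems = c("cisplatin", "clonidine", "salicylate", "metformin",
              "heparin", "ibuprofen", "glucosamine", "docetaxel",
              "rifampin", "naproxen"),
    caps = c("TPGS", "MTT", "DMSO", "EGCG", "ATP", "NADPH"),
    headers = c("CONCLUSION", "RESULTS", "METHODS", "BACKGROUND",
                "OBJECTIVE"),
    capStems = c("Glucose", "Insulin", "Lactate", "Creatinine"),
    affixes = c("hyper", "anti", "amino"),
    affixStems = c("insulinaemia", "herpetic", "glycaemia", "phylline"),
    spacePairs = list(c("tetrazolium", "bromide"),
                      c("ethylene", "glycol"),
                      c("sodium", "chloride")))

#' Phenomenon kinds emitted by the synthetic generator
#'
#' @return character vector of the seven phenomenon kinds.
#' @export
phenomenonKinds <- function()
    c("simple_entity", "hyphen_conjoined", "internal_space_entity",
      "paren_formula", "plural_form", "affix_containment", "case_fused")

## Phenomena that provably break whitespace-token boundaries by
## construction (an entity boundary falls strictly inside a whitespace
## token). internal_space_entity and simple_entity boundaries coincide
## with whitespace boundaries and are therefore not in this set.
.WS_BREAKING <- c("hyphen_conjoined", "paren_formula", "plural_form",
                  "affix_containment", "case_fused")

## Emit one phenomenon instance: a chunk of text (no leading/trailing
## space) plus gold spans relative to the chunk start.
.emitPhenomenon <- function(kind) {
    pick <- function(x) x[sample.int(length(x), 1L)]
    rel <- function(text, s, e, surface, cls)
        data.frame(start = s, end = e, surface = surface,
                   entityClass = cls, kind = kind,
                   stringsAsFactors = FALSE)
    switch(kind,
    simple_entity = {
        stem <- pick(.SYN$stems)
        list(text = stem,
             spans = rel(stem, 0L, nchar(stem), stem, "TRIVIAL"),
             entityLex = stem, chemLex = character(0))
    },
    hyphen_conjoined = {
        abbr <- pick(.SYN$caps); stem <- pick(.SYN$stems)
        text <- paste0(abbr, "-", stem)
        spans <- rbind(
            rel(text, 0L, nchar(abbr), abbr, "ABBREVIATION"),
            rel(text, nchar(abbr) + 1L, nchar(text), stem, "TRIVIAL"))
        list(text = text, spans = spans,
             entityLex = c(abbr, stem), chemLex = character(0))
    },
    internal_space_entity = {
        pair <- .SYN$spacePairs[[sample.int(length(.SYN$spacePairs), 1L)]]
        text <- paste(pair, collapse = " ")
        list(text = text,
             spans = rel(text, 0L, nchar(text), text, "SYSTEMATIC"),
             entityLex = pair, chemLex = character(0))
    },
    paren_formula = {
        host <- pick(.SYN$fillers)
        lo <- sample.int(8L, 1L); hi <- lo + sample.int(9L - lo, 1L)
        formula <- sprintf("(%d-%d)", lo, hi)
        text <- paste0(host, formula)
        list(text = text,
             spans = rel(text, nchar(host), nchar(text), formula,
                         "FORMULA"),
             entityLex = character(0), chemLex = character(0))
    },
    plural_form = {
        stem <- pick(.SYN$stems)
        suf <- pick(c("s", "es"))
        text <- paste0(stem, suf)
        list(text = text,
             spans = rel(text, 0L, nchar(stem), stem, "TRIVIAL"),
             entityLex = character(0), chemLex = stem)
    },
    affix_containment = {
        affix <- pick(.SYN$affixes); stem <- pick(.SYN$affixStems)
        text <- paste0(affix, stem)
        list(text = text,
             spans = rel(text, nchar(affix), nchar(text), stem, "FAMILY"),
             entityLex = character(0), chemLex = character(0))
    },
    case_fused = {
        header <- pick(.SYN$headers); stem <- pick(.SYN$capStems)
        text <- paste0(header, stem)
        list(text = text,
             spans = rel(text, nchar(header), nchar(text), stem,
                         "TRIVIAL"),
             entityLex = character(0), chemLex = character(0))
    },
    stop("unknown phenomenon kind: ", kind, call. = FALSE))
}

#' Generate a seeded synthetic annotated corpus
#'
#' Produces documents in the abstracts dialect (title and body joined by a
#' tab), gold entity spans, a manifest recording each entity's phenomenon
#' kind, and the lexica the rule tokenizer needs to repair the lexicon-gated
#' phenomena (plural bases injected into the chemical-name lexicon, affixes
#' into the affix lexicon, entity surfaces into the entity lexicon). Every
#' emitted span's surface is verified against the text before return, and
#' the output is a deterministic function of \code{seed}.
#'
#' @param seed integer RNG seed.
#' @param nDocs number of documents (>= 0).
#' @param weights named non-negative sampling weights over
#'   \code{\link{phenomenonKinds}}; kinds with weight 0 are never emitted.
#' @param entitiesPerDoc integer range (length 2) of phenomenon instances
#'   sampled per document.
#' @return a list with elements \code{documents} (\code{docId},
#'   \code{text}), \code{annotations} (entity-span \code{data.frame}),
#'   \code{manifest} (annotations plus \code{kind}), and \code{lexica}
#'   (list of \code{entities}, \code{affixes}, \code{chemNames}
#'   \code{\linkS4class{Lexicon}} objects).
#' @examples
#' syn <- generateCorpus(42, nDocs = 3)
#' head(syn$manifest)
#' @export
generateCorpus <- function(seed, nDocs = 50L,
                           weights = stats::setNames(
                               rep(1, length(phenomenonKinds())),
                               phenomenonKinds()),
                           entitiesPerDoc = c(2L, 4L)) {
    stopifnot(nDocs >= 0L, length(entitiesPerDoc) == 2L,
              entitiesPerDoc[1L] >= 1L,
              entitiesPerDoc[2L] >= entitiesPerDoc[1L])
    if (is.null(names(weights)) ||
        !all(names(weights) %in% phenomenonKinds()))
        stop("'weights' must be named by phenomenon kinds", call. = FALSE)
    w <- stats::setNames(rep(0, length(phenomenonKinds())),
                         phenomenonKinds())
    w[names(weights)] <- weights
    if (any(w < 0) || sum(w) <= 0)
        stop("weights must be non-negative with positive sum",
             call. = FALSE)
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(as.integer(seed))

    ids <- character(0); texts <- character(0)
    manifest <- list()
    entityLex <- character(0); chemLex <- character(0)

    for (d in seq_len(nDocs)) {
        id <- sprintf("SYN%04d", d)
        title <- paste("synthetic record", d)
        body <- character(0)
        cursor <- nchar(title) + 1L      # 0-based offset of body start
        nEntRange <- seq(entitiesPerDoc[1L], entitiesPerDoc[2L])
        nEnt <- nEntRange[sample.int(length(nEntRange), 1L)]
        kinds <- sample(phenomenonKinds(), nEnt, replace = TRUE, prob = w)
        for (k in seq_len(nEnt)) {
            nFill <- sample.int(3L, 1L)
            fill <- sample(.SYN$fillers, nFill, replace = TRUE)
            for (f in fill) {
                body <- c(body, f)
                cursor <- cursor + nchar(f) + 1L
            }
            em <- .emitPhenomenon(kinds[k])
            sp <- em$spans
            sp$start <- sp$start + cursor
            sp$end <- sp$end + cursor
            sp <- cbind(data.frame(docId = id, stringsAsFactors = FALSE),
                        sp)
            manifest[[length(manifest) + 1L]] <- sp
            entityLex <- c(entityLex, em$entityLex)
            chemLex <- c(chemLex, em$chemLex)
            body <- c(body, em$text)
            cursor <- cursor + nchar(em$text) + 1L
        }
        tail <- sample(.SYN$fillers, 2L, replace = TRUE)
        text <- paste0(title, "\t", paste(c(body, tail), collapse = " "))
        ids <- c(ids, id); texts <- c(texts, text)
    }

    documents <- data.frame(docId = ids, text = texts,
                            stringsAsFactors = FALSE)
    manifest <- if (length(manifest)) do.call(rbind, manifest)
                else cbind(emptyEntityFrame(),
                           data.frame(kind = character(0)))
    rownames(manifest) <- NULL
    ## gold-offset validity: surface must equal the text slice
    if (nrow(manifest)) {
        txt <- documents$text[match(manifest$docId, documents$docId)]
        slice <- substr(txt, manifest$start + 1L, manifest$end)
        stopifnot(identical(slice, manifest$surface))
    }
    annotations <- manifest[, c("docId", "start", "end", "surface",
                                "entityClass"), drop = FALSE]
    list(documents = documents,
         annotations = annotations,
         manifest = manifest,
         lexica = list(
             entities = Lexicon(entityLex, ignoreCase = FALSE,
                                name = "synthetic entities"),
             affixes = Lexicon(.SYN$affixes, ignoreCase = TRUE,
                               name = "synthetic affixes"),
             chemNames = Lexicon(chemLex, ignoreCase = TRUE,
                                 name = "synthetic chemical names")))
}

#' Expected boundary violations for a generated corpus
#'
#' Test oracle derived from the manifest alone: under the whitespace
#' baseline, every entity whose phenomenon fuses an entity boundary into
#' the interior of a whitespace token (hyphen-conjoined, parenthesized
#' formula fused to adjacent text, plural form, affix containment, case
#' fusion) is incorrectly segmented; entities whose boundaries coincide
#' with whitespace boundaries are not. Under the rule tokenizer, run with
#' the lexica returned by \code{\link{generateCorpus}}, every covered
#' phenomenon is repaired, so the expected count is 0.
#'
#' @param manifest the \code{manifest} from \code{\link{generateCorpus}}.
#' @param tokenizerName \code{"rules"} or \code{"whitespace"}.
#' @return integer expected NISE.
#' @export
expectedViolations <- function(manifest, tokenizerName) {
    stopifnot(is.data.frame(manifest), "kind" %in% names(manifest))
    switch(tokenizerName,
           whitespace = sum(manifest$kind %in% .WS_BREAKING),
           rules = 0L,
           stop("unknown tokenizer name: ", tokenizerName,
                call. = FALSE))
}

#' Write a generated corpus to disk
#'
#' Writes the abstracts TSV, annotation TSV, the three lexicon files and a
#' JSON manifest into \code{dir}.
#'
#' @param corpus the list returned by \code{\link{generateCorpus}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
    stopifnot(all(c("documents", "annotations", "manifest", "lexica") %in%
                  names(corpus)))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeAbstracts(corpus$documents, file.path(dir, "abstracts.tsv"))
    writeAnnotations(corpus$annotations,
                     file.path(dir, "annotations.tsv"))
    writeLexicon(corpus$lexica$entities, file.path(dir, "entities.txt"))
    writeLexicon(corpus$lexica$affixes, file.path(dir, "affixes.txt"))
    writeLexicon(corpus$lexica$chemNames,
                 file.path(dir, "chem_names.txt"))
    jsonlite::write_json(corpus$manifest,
                         file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE)
    invisible(dir)
}
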