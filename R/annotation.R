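## Gold entity spans travel as a data.frame with columns
## docId, start, end (0-based half-open), surface, entityClass.

.checkEntityFrame <- function(entities) {
    req <- c("docId", "start", "end", "surface", "entityClass")
    if (!is.data.frame(entities) || !all(req %in% names(entities)))
        stop("entities must be a data.frame with columns ",
             paste(req, collapse = ", "), call. = FALSE)
    if (nrow(entities) && any(entities$end <= entities$start))
        stop("entity spans must satisfy end > start", call. = FALSE)
    if (nrow(entities) && any(entities$start < 0))
        stop("entity offsets must be non-negative", call. = FALSE)
    invisible(entities)
}

#' An empty gold entity span table
#'
#' @return a zero-row \code{data.frame} with the entity-span columns
#'   \code{docId}, \code{start}, \code{end} (0-based half-open),
#'   \code{surface}, \code{entityClass}.
#' @export
emptyEntityFrame <- function() {
    data.frame(docId = character(0), start = integer(0), end = integer(0),
               surface = character(0), entityClass = character(0),
               stringsAsFactors = FALSE)
}

#' Align tokens to gold entity spans and emit IOB labels
#'
#' An entity is \emph{correctly segmented} iff some token starts exactly at
#' its start offset, some token ends exactly at its end offset, and every
#' token overlapping the span lies wholly inside it. Correct entities label
#' their covered tokens \code{B-<class>} (first) and \code{I-<class>}
#' (rest); incorrectly segmented entities are returned in the violation
#' table and contribute no labels (tokens strictly inside them stay
#' \code{O}), reflecting that a sequence classifier cannot learn a span
#' whose boundaries do not exist in its input.
#'
#' @param seq a \code{\linkS4class{TokenSequence}}.
#' @param entities gold spans for this document: a \code{data.frame} with
#'   columns \code{docId}, \code{start}, \code{end} (0-based half-open),
#'   \code{surface}, \code{entityClass}. Rows for other documents are
#'   ignored. Overlapping spans are an error.
#' @return a list with elements \code{tokens} (a \code{data.frame}:
#'   \code{docId}, \code{start}, \code{end}, \code{surface}, \code{label})
#'   and \code{violations} (the incorrectly segmented subset of
#'   \code{entities}).
#' @examples
#' ts <- tokenize("inhibition of NF-kappa B activation", "d1")
#' gold <- data.frame(docId = "d1", start = 14, end = 24,
#'                    surface = "NF-kappa B", entityClass = "CHEMICAL")
#' alignAndLabel(ts, gold)$tokens$label
#' @export
alignAndLabel <- function(seq, entities = emptyEntityFrame()) {
    stopifnot(is(seq, "TokenSequence"))
    .checkEntityFrame(entities)
    ent <- entities[entities$docId == seq@docId, , drop = FALSE]
    if (nrow(ent) && any(ent$end > nchar(seq@sourceText)))
        stop("entity span beyond document bounds in '", seq@docId, "'",
             call. = FALSE)
    if (nrow(ent) > 1L) {
        o <- order(ent$start, ent$end)
        eo <- ent[o, ]
        clash <- which(eo$start[-1L] < eo$end[-nrow(eo)])
        if (length(clash))
            stop(sprintf(
                "overlapping gold entities in '%s': [%d,%d) '%s' and [%d,%d) '%s'",
                seq@docId, eo$start[clash[1L]], eo$end[clash[1L]],
                eo$surface[clash[1L]], eo$start[clash[1L] + 1L],
                eo$end[clash[1L] + 1L], eo$surface[clash[1L] + 1L]),
                call. = FALSE)
    }
    tS <- tokenStarts(seq)          # 0-based half-open
    tE <- tokenEnds(seq)
    labels <- rep("O", length(tS))
    bad <- logical(nrow(ent))
    for (k in seq_len(nrow(ent))) {
        s <- ent$start[k]; e <- ent$end[k]
        overlap <- which(tS < e & tE > s)
        ok <- any(tS == s) && any(tE == e) &&
            length(overlap) > 0L &&
            all(tS[overlap] >= s & tE[overlap] <= e)
        if (ok) {
            inside <- overlap
            labels[inside[1L]] <- paste0("B-", ent$entityClass[k])
            if (length(inside) > 1L)
                labels[inside[-1L]] <- paste0("I-", ent$entityClass[k])
        } else {
            bad[k] <- TRUE
        }
    }
    tok <- as.data.frame(seq)
    tok$label <- labels
    list(tokens = tok, violations = ent[bad, , drop = FALSE])
}

#' Segmentation-quality statistics for one tokenizer over a corpus
#'
#' Computes the three corpus-level quantities used to compare tokenizers:
#' NT, the total number of tokens; ATL, the mean token surface length in
#' characters; and NISE, the number of incorrectly segmented entities —
#' gold spans whose boundaries do not coincide with token boundaries (per
#' \code{\link{alignAndLabel}}). Each gold annotation row is counted
#' independently.
#'
#' @param seqs a list of \code{\linkS4class{TokenSequence}} objects, one
#'   per document.
#' @param entities gold spans for the whole corpus (entity-span
#'   \code{data.frame}); every \code{docId} it references must be present
#'   in \code{seqs}.
#' @param tokenizerName label recorded in the result.
#' @return a one-row \code{data.frame}: \code{tokenizer}, \code{NT},
#'   \code{ATL}, \code{NISE}.
#' @examples
#' seqs <- list(tokenize("NaCl in water", "d1"))
#' computeStats(seqs, emptyEntityFrame(), "rules")
#' @export
computeStats <- function(seqs, entities = emptyEntityFrame(),
                         tokenizerName = "tokenizer") {
    stopifnot(is.list(seqs),
              all(vapply(seqs, is, logical(1), "TokenSequence")))
    .checkEntityFrame(entities)
    ids <- vapply(seqs, docId, character(1))
    if (anyDuplicated(ids))
        stop("duplicate document ids in corpus", call. = FALSE)
    missing <- setdiff(unique(entities$docId), ids)
    if (length(missing))
        stop("entities reference unknown document id(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    allLen <- unlist(lapply(seqs, function(s) nchar(tokenSurfaces(s))))
    nt <- length(allLen)
    atl <- if (nt) mean(allLen) else NA_real_
    nise <- 0L
    for (s in seqs) {
        ent <- entities[entities$docId == docId(s), , drop = FALSE]
        if (nrow(ent))
            nise <- nise + nrow(alignAndLabel(s, ent)$violations)
    }
    data.frame(tokenizer = tokenizerName, NT = nt, ATL = atl, NISE = nise,
               stringsAsFactors = FALSE)
}

#' Check IOB label sequence validity
#'
#' A label sequence is valid when every \code{I-X} directly follows a
#' \code{B-X} or \code{I-X} of the same class.
#'
#' @param labels character vector of IOB labels (\code{O}, \code{B-X},
#'   \code{I-X}).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
isValidIOB <- function(labels) {
    if (!length(labels)) return(TRUE)
    prev <- c("O", labels[-length(labels)])
    iTag <- startsWith(labels, "I-")
    cls <- sub("^[BI]-", "", labels)
    prevCls <- sub("^[BI]-", "", prev)
    all(!iTag | (prev != "O" & prevCls == cls))
}
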