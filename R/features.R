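## The 25 features, in 7 groups of sizes 3, 2, 8, 3, 7, 1, 1.
.FEATURE_GROUPS <- c(
    has_right_space = "space", has_left_space = "space",
    has_both_spaces = "space",
    prev_token = "context", next_token = "context",
    prefix1 = "ngram_affix", prefix2 = "ngram_affix",
    prefix3 = "ngram_affix", prefix4 = "ngram_affix",
    suffix1 = "ngram_affix", suffix2 = "ngram_affix",
    suffix3 = "ngram_affix", suffix4 = "ngram_affix",
    word_shape = "word_shape", digital_shape = "word_shape",
    summarized_shape = "word_shape",
    all_uppercase = "orthographic", has_slash = "orthographic",
    has_punctuation = "orthographic", has_real_number = "orthographic",
    starts_with_digit = "orthographic",
    starts_with_uppercase = "orthographic",
    more_than_2_uppercase = "orthographic",
    token_length = "length",
    has_chem_affix = "chem_affix")

#' Names and groups of the token feature set
#'
#' The extractor emits exactly 25 named features partitioned into 7 groups:
#' space (3), context (2), n-gram affixes (8), word shapes (3),
#' orthographic (7), token length (1) and chemical affix (1).
#'
#' @return \code{featureNames}: character vector of the 25 feature names in
#'   export order; \code{featureGroups}: named character vector mapping each
#'   feature to its group.
#' @export
featureNames <- function() names(.FEATURE_GROUPS)

#' @rdname featureNames
#' @export
featureGroups <- function() .FEATURE_GROUPS

#' Space features of a token in context
#'
#' Whether whitespace (or a document boundary, which counts as space)
#' adjoins the token on the right, on the left, and on both sides.
#'
#' @param seq a \code{\linkS4class{TokenSequence}}.
#' @param i token index (1-based).
#' @return named logical vector \code{has_right_space},
#'   \code{has_left_space}, \code{has_both_spaces}.
#' @export
spaceFeatures <- function(seq, i) {
    stopifnot(is(seq, "TokenSequence"), i >= 1L, i <= length(seq@ranges))
    txt <- seq@sourceText
    s <- IRanges::start(seq@ranges)[i]; e <- IRanges::end(seq@ranges)[i]
    leftCh <- if (s == 1L) " " else substr(txt, s - 1L, s - 1L)
    rightCh <- if (e == nchar(txt)) " " else substr(txt, e + 1L, e + 1L)
    left <- grepl("[[:space:]]", leftCh)
    right <- grepl("[[:space:]]", rightCh)
    c(has_right_space = right, has_left_space = left,
      has_both_spaces = left && right)
}

#' Context words of a token
#'
#' The surfaces of the tokens immediately before and after position
#' \code{i}; sequence boundaries yield the sentinel \code{"<PAD>"}.
#'
#' @inheritParams spaceFeatures
#' @return named character vector \code{prev_token}, \code{next_token}.
#' @export
contextWords <- function(seq, i) {
    stopifnot(is(seq, "TokenSequence"), i >= 1L, i <= length(seq@ranges))
    surf <- tokenSurfaces(seq)
    c(prev_token = if (i > 1L) surf[i - 1L] else "<PAD>",
      next_token = if (i < length(surf)) surf[i + 1L] else "<PAD>")
}

#' Character n-gram affixes of a token surface
#'
#' Prefixes and suffixes of lengths 1 to 4. When the surface is shorter
#' than \code{n}, the whole surface is used (kept human-readable rather
#' than padded).
#'
#' @param surface a non-empty token string.
#' @return named character vector \code{prefix1..4}, \code{suffix1..4}.
#' @examples
#' ngramAffixes("acid")
#' @export
ngramAffixes <- function(surface) {
    stopifnot(is.character(surface), length(surface) == 1L, nzchar(surface))
    len <- nchar(surface)
    pre <- vapply(1:4, function(n) substr(surface, 1L, min(n, len)), "")
    suf <- vapply(1:4, function(n)
        substr(surface, max(1L, len - n + 1L), len), "")
    stats::setNames(c(pre, suf),
                    c(paste0("prefix", 1:4), paste0("suffix", 1:4)))
}

#' Word-shape features of a token surface
#'
#' Three abstractions of the surface: \code{word_shape}, the counts of
#' uppercase, lowercase, digit, punctuation and Greek (non-ASCII letter)
#' characters serialized \code{"U:a|L:b|D:c|P:d|G:e"};
#' \code{digital_shape}, the per-character class string over the alphabet
#' \code{A a 0 p g}; and \code{summarized_shape}, the digital shape with
#' runs of equal classes collapsed.
#'
#' @param surface a non-empty token string.
#' @return named character vector of the three shapes.
#' @examples
#' wordShapes("NaCL")   # digital "AaAA", summarized "AaA"
#' @export
wordShapes <- function(surface) {
    stopifnot(is.character(surface), length(surface) == 1L, nzchar(surface))
    cat <- .charCategories(strsplit(surface, "", fixed = TRUE)[[1L]])
    counts <- vapply(c("U", "L", "D", "P", "G"),
                     function(k) sum(cat == k), integer(1))
    shape <- sprintf("U:%d|L:%d|D:%d|P:%d|G:%d",
                     counts["U"], counts["L"], counts["D"], counts["P"],
                     counts["G"])
    digital <- paste(c(U = "A", L = "a", D = "0", P = "p", G = "g")[cat],
                     collapse = "")
    summarized <- paste(rle(strsplit(digital, "", fixed = TRUE)[[1L]])$values,
                        collapse = "")
    c(word_shape = shape, digital_shape = digital,
      summarized_shape = summarized)
}

#' Orthographic features of a token surface
#'
#' Seven booleans: all characters uppercase letters; contains a slash;
#' contains punctuation; contains a real number (a digit run, optionally
#' with one decimal point); starts with a digit; starts with an uppercase
#' letter; has more than 2 uppercase letters.
#'
#' @param surface a non-empty token string.
#' @return named logical vector of length 7.
#' @examples
#' orthographicFeatures("MTT")
#' @export
orthographicFeatures <- function(surface) {
    stopifnot(is.character(surface), length(surface) == 1L, nzchar(surface))
    cat <- .charCategories(strsplit(surface, "", fixed = TRUE)[[1L]])
    c(all_uppercase = all(cat == "U"),
      has_slash = grepl("/", surface, fixed = TRUE),
      has_punctuation = any(cat == "P"),
      has_real_number = grepl("[0-9]+(\\.[0-9]+)?", surface),
      starts_with_digit = cat[1L] == "D",
      starts_with_uppercase = cat[1L] == "U",
      more_than_2_uppercase = sum(cat == "U") > 2L)
}

#' Chemical-affix flag
#'
#' \code{TRUE} iff any lexicon affix occurs case-insensitively as a prefix
#' or suffix of the surface.
#'
#' @param surface a token string.
#' @param affixes chemical-affix \code{\linkS4class{Lexicon}}.
#' @return a logical scalar.
#' @examples
#' chemAffixFlag("chloride", Lexicon("ide"))
#' @export
chemAffixFlag <- function(surface, affixes) {
    stopifnot(is.character(surface), length(surface) == 1L,
              is(affixes, "Lexicon"))
    ents <- tolower(affixes@entries)
    if (!length(ents)) return(FALSE)
    s <- tolower(surface)
    any(startsWith(s, ents) | endsWith(s, ents))
}

#' Extract the full 25-feature vector of one token
#'
#' Concatenates all seven groups for the token at position \code{i}. The
#' extraction is deterministic and never inspects labels.
#'
#' @inheritParams spaceFeatures
#' @param affixes chemical-affix \code{\linkS4class{Lexicon}} used by the
#'   \code{has_chem_affix} feature.
#' @return a named list of 25 features, with attribute \code{"groups"}
#'   giving each feature's group.
#' @examples
#' ts <- tokenize("NaCL here", chemNames = Lexicon("NaCL"))
#' fv <- extractFeatures(ts, 1)
#' length(fv)  # 25
#' @export
extractFeatures <- function(seq, i, affixes = Lexicon()) {
    stopifnot(is(seq, "TokenSequence"))
    if (!(is.numeric(i) && length(i) == 1L && i >= 1L &&
          i <= length(seq@ranges)))
        stop("token index out of range: ", i, call. = FALSE)
    surf <- tokenSurfaces(seq)[i]
    out <- c(as.list(spaceFeatures(seq, i)),
             as.list(contextWords(seq, i)),
             as.list(ngramAffixes(surf)),
             as.list(wordShapes(surf)),
             as.list(orthographicFeatures(surf)),
             list(token_length = nchar(surf)),
             list(has_chem_affix = chemAffixFlag(surf, affixes)))
    stopifnot(identical(names(out), featureNames()))
    attr(out, "groups") <- .FEATURE_GROUPS
    out
}

#' Feature table for a whole token sequence
#'
#' One row per token: \code{docId}, \code{start}, \code{end},
#' \code{surface}, then the 25 features in the order of
#' \code{\link{featureNames}}, and optionally a \code{label} column.
#'
#' @param seq a \code{\linkS4class{TokenSequence}}.
#' @param affixes chemical-affix \code{\linkS4class{Lexicon}}.
#' @param labels optional character vector of IOB labels, one per token.
#' @return a \code{data.frame}.
#' @export
featureTable <- function(seq, affixes = Lexicon(), labels = NULL) {
    stopifnot(is(seq, "TokenSequence"))
    n <- length(seq@ranges)
    if (!is.null(labels)) stopifnot(length(labels) == n)
    base <- as.data.frame(seq)
    if (n == 0L) {
        feats <- as.data.frame(stats::setNames(
            rep(list(logical(0)), length(featureNames())), featureNames()))
        return(cbind(base, feats))
    }
    rows <- lapply(seq_len(n), function(i) {
        fv <- extractFeatures(seq, i, affixes)
        attr(fv, "groups") <- NULL
        as.data.frame(fv, stringsAsFactors = FALSE)
    })
    out <- cbind(base, do.call(rbind, rows))
    if (!is.null(labels)) out$label <- labels
    rownames(out) <- NULL
    out
}

#' Write / read feature tables
#'
#' Tab-separated, one token per line, with a header giving the stable
#' column order. Logical features are written as \code{1}/\code{0};
#' \code{readFeatures} restores the original column types, so a
#' write-then-read round trip reproduces the table exactly.
#'
#' @param features a \code{data.frame} from \code{\link{featureTable}}.
#' @param path output (input) path.
#' @return \code{writeFeatures}: \code{path}, invisibly;
#'   \code{readFeatures}: the feature \code{data.frame}.
#' @export
writeFeatures <- function(features, path) {
    stopifnot(is.data.frame(features))
    out <- features
    for (j in seq_along(out))
        if (is.logical(out[[j]])) out[[j]] <- as.integer(out[[j]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
    if (!file.exists(path))
        stop("feature file not found: ", path, call. = FALSE)
    out <- utils::read.table(path, sep = "\t", header = TRUE,
                             quote = "", comment.char = "",
                             colClasses = "character",
                             stringsAsFactors = FALSE, encoding = "UTF-8")
    logicalCols <- names(.FEATURE_GROUPS)[.FEATURE_GROUPS %in%
                                          c("space", "orthographic",
                                            "chem_affix")]
    for (nm in intersect(logicalCols, names(out)))
        out[[nm]] <- as.integer(out[[nm]]) == 1L
    for (nm in intersect(c("start", "end", "token_length"), names(out)))
        out[[nm]] <- as.integer(out[[nm]])
    out
}
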