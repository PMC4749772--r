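## Step-3 merge rules. All operate on offset vectors and rebuild the
## TokenSequence; merges only ever join source-contiguous tokens, so no
## merged surface can acquire whitespace.

.isNumeric <- function(surf) grepl("^[0-9]+$", surf)

## A rule-1 numeric chain: digits possibly joined by single separators
## (starts and ends with a digit, no two adjacent separators).
.isNumericChain <- function(surfaces, separators) {
    vapply(surfaces, function(s) {
        chars <- strsplit(s, "", fixed = TRUE)[[1L]]
        n <- length(chars)
        if (n == 0L) return(FALSE)
        isD <- grepl("^[0-9]$", chars)
        isSep <- chars %in% separators
        isD[1L] && isD[n] && all(isD | isSep) &&
            (n == 1L || !any(!isD[-n] & !isD[-1L]))
    }, logical(1), USE.NAMES = FALSE)
}

.contiguous <- function(s, e) e[-length(e)] + 1L == s[-1L]

#' Merge numeric tokens joined by separators (rule 1)
#'
#' Maximal alternating chains numeric, separator, numeric, ..., numeric —
#' where each separator is a single-character token from the configured set
#' and all pieces are source-contiguous — are merged back into one token:
#' \code{125 , 12 , 12} becomes \code{125,12,12}.
#'
#' @param seq a \code{\linkS4class{TokenSequence}}.
#' @param config a \code{\linkS4class{TokenizerConfig}}.
#' @return a \code{TokenSequence}.
#' @export
mergeNumericRuns <- function(seq, config = tokenizerConfig()) {
    stopifnot(is(seq, "TokenSequence"), is(config, "TokenizerConfig"))
    n <- length(seq@ranges)
    if (n < 3L) return(seq)
    s <- IRanges::start(seq@ranges); e <- IRanges::end(seq@ranges)
    surf <- tokenSurfaces(seq)
    isNum <- .isNumeric(surf)
    isSep <- nchar(surf) == 1L & surf %in% config@separators
    contig <- c(e[-n] + 1L == s[-1L], FALSE)   # contig[i]: i touches i+1
    ns <- integer(0); ne <- integer(0)
    i <- 1L
    while (i <= n) {
        j <- i
        if (isNum[i]) {
            while (j + 2L <= n && isSep[j + 1L] && isNum[j + 2L] &&
                   contig[j] && contig[j + 1L])
                j <- j + 2L
        }
        ns <- c(ns, s[i]); ne <- c(ne, e[j])
        i <- j + 1L
    }
    .tokenSeq(seq@docId, seq@sourceText, ns, ne)
}

#' Absorb balanced containers around numeric chains (rule 2)
#'
#' When a numeric token or a rule-1 numeric chain is immediately preceded by
#' an opening container and followed by its matching closer, all three
#' source-contiguous tokens merge: \code{( 1-3 )} becomes \code{(1-3)}.
#' Containers around non-numeric content are left alone.
#'
#' @inheritParams mergeNumericRuns
#' @return a \code{TokenSequence}.
#' @export
mergeBalancedContainers <- function(seq, config = tokenizerConfig()) {
    stopifnot(is(seq, "TokenSequence"), is(config, "TokenizerConfig"))
    n <- length(seq@ranges)
    if (n < 3L) return(seq)
    s <- IRanges::start(seq@ranges); e <- IRanges::end(seq@ranges)
    surf <- tokenSurfaces(seq)
    chain <- .isNumericChain(surf, config@separators)
    openIdx <- match(surf, config@openers)
    closeIdx <- match(surf, config@closers)
    contig <- c(e[-n] + 1L == s[-1L], FALSE)
    ns <- integer(0); ne <- integer(0)
    i <- 1L
    while (i <= n) {
        if (i + 2L <= n && !is.na(openIdx[i]) && chain[i + 1L] &&
            !is.na(closeIdx[i + 2L]) && openIdx[i] == closeIdx[i + 2L] &&
            contig[i] && contig[i + 1L]) {
            ns <- c(ns, s[i]); ne <- c(ne, e[i + 2L])
            i <- i + 3L
        } else {
            ns <- c(ns, s[i]); ne <- c(ne, e[i])
            i <- i + 1L
        }
    }
    .tokenSeq(seq@docId, seq@sourceText, ns, ne)
}

#' Rejoin a single uppercase letter to a following lowercase token (rule 3)
#'
#' The delimiter step deliberately over-splits words written with an initial
#' capital ("Common" becomes "C" + "ommon"); this rule repairs them: a token
#' that is exactly one uppercase letter, source-contiguous with a following
#' all-lowercase token, merges with it. Applied left to right in one pass.
#'
#' @param seq a \code{\linkS4class{TokenSequence}}.
#' @return a \code{TokenSequence}.
#' @export
mergeSingleUppercase <- function(seq) {
    stopifnot(is(seq, "TokenSequence"))
    n <- length(seq@ranges)
    if (n < 2L) return(seq)
    s <- IRanges::start(seq@ranges); e <- IRanges::end(seq@ranges)
    surf <- tokenSurfaces(seq)
    isCap <- grepl("^[A-Z]$", surf)
    isLow <- grepl("^[a-z]+$", surf)
    contig <- c(e[-n] + 1L == s[-1L], FALSE)
    ns <- integer(0); ne <- integer(0)
    i <- 1L
    while (i <= n) {
        if (i < n && isCap[i] && isLow[i + 1L] && contig[i]) {
            ns <- c(ns, s[i]); ne <- c(ne, e[i + 1L])
            i <- i + 2L
        } else {
            ns <- c(ns, s[i]); ne <- c(ne, e[i])
            i <- i + 1L
        }
    }
    .tokenSeq(seq@docId, seq@sourceText, ns, ne)
}

#' Merge consecutive tokens forming a known chemical name (rule 4)
#'
#' A sliding window of up to \code{rule4Window} (default 5) consecutive,
#' source-contiguous tokens is searched case-insensitively against the
#' known-chemical-name lexicon. Scanning left to right, windows are tried
#' longest first; on a hit the tokens merge and scanning resumes after the
#' merged token (greedy, leftmost-longest): \code{Na CL} with "NaCL" known
#' becomes \code{NaCL}.
#'
#' @param seq a \code{\linkS4class{TokenSequence}}.
#' @param chemNames known-chemical-name \code{\linkS4class{Lexicon}}.
#' @param config a \code{\linkS4class{TokenizerConfig}}.
#' @return a \code{TokenSequence}.
#' @export
mergeKnownNames <- function(seq, chemNames, config = tokenizerConfig()) {
    stopifnot(is(seq, "TokenSequence"), is(chemNames, "Lexicon"),
              is(config, "TokenizerConfig"))
    n <- length(seq@ranges)
    if (n < 2L || length(chemNames@entries) == 0L) return(seq)
    s <- IRanges::start(seq@ranges); e <- IRanges::end(seq@ranges)
    surf <- tokenSurfaces(seq)
    known <- tolower(chemNames@entries)
    contig <- c(e[-n] + 1L == s[-1L], FALSE)
    ns <- integer(0); ne <- integer(0)
    i <- 1L
    while (i <= n) {
        merged <- FALSE
        for (w in seq(min(config@rule4Window, n - i + 1L), 2L)) {
            if (w < 2L) break
            j <- i + w - 1L
            if (!all(contig[i:(j - 1L)])) next
            cand <- tolower(paste(surf[i:j], collapse = ""))
            if (cand %in% known) {
                ns <- c(ns, s[i]); ne <- c(ne, e[j])
                i <- j + 1L
                merged <- TRUE
                break
            }
        }
        if (!merged) {
            ns <- c(ns, s[i]); ne <- c(ne, e[i])
            i <- i + 1L
        }
    }
    .tokenSeq(seq@docId, seq@sourceText, ns, ne)
}

#' Split plural tokens into base form and plurality suffix (rule 5)
#'
#' Entities frequently occur pluralized in text ("salicylates") while the
#' gold annotation covers the singular. A token ending in a plural suffix
#' (tried in the configured order: "ies", "es", "s") whose raw-stripped base
#' is found in the entity lexicon (under the gate's case policy) or in the
#' known-chemical-name lexicon (case-insensitively) is split into a base
#' token and a suffix token partitioning its offsets. The lexicon gate keeps
#' ordinary English ("is", "its") intact.
#'
#' @param seq a \code{\linkS4class{TokenSequence}}.
#' @param entities entity-surface \code{\linkS4class{Lexicon}}.
#' @param chemNames known-chemical-name \code{\linkS4class{Lexicon}}.
#' @param config a \code{\linkS4class{TokenizerConfig}}.
#' @return a \code{TokenSequence}.
#' @export
splitPluralForms <- function(seq, entities = Lexicon(),
                             chemNames = Lexicon(),
                             config = tokenizerConfig()) {
    stopifnot(is(seq, "TokenSequence"), is(entities, "Lexicon"),
              is(chemNames, "Lexicon"), is(config, "TokenizerConfig"))
    n <- length(seq@ranges)
    if (n == 0L) return(seq)
    s <- IRanges::start(seq@ranges); e <- IRanges::end(seq@ranges)
    surf <- tokenSurfaces(seq)
    ns <- integer(0); ne <- integer(0)
    for (i in seq_len(n)) {
        cutAt <- NA_integer_
        for (suf in config@pluralSuffixes) {
            k <- nchar(suf)
            if (nchar(surf[i]) > k && endsWith(surf[i], suf)) {
                base <- substr(surf[i], 1L, nchar(surf[i]) - k)
                if (lexiconContains(entities, base,
                        ignoreCase = config@entityGateIgnoreCase) ||
                    lexiconContains(chemNames, base, ignoreCase = TRUE)) {
                    cutAt <- nchar(surf[i]) - k
                    break
                }
            }
        }
        if (is.na(cutAt)) {
            ns <- c(ns, s[i]); ne <- c(ne, e[i])
        } else {
            ns <- c(ns, s[i], s[i] + cutAt)
            ne <- c(ne, s[i] + cutAt - 1L, e[i])
        }
    }
    .tokenSeq(seq@docId, seq@sourceText, ns, ne)
}
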