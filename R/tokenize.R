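#' Tokenize a document with the full rule pipeline
#'
#' Runs the complete three-step segmentation: (1) whitespace split;
#' (2) affix split and entity-gated delimiter/digit/case splitting;
#' (3) the five merge/repair rules — numeric-chain merge, balanced-container
#' merge, single-uppercase rejoin, known-chemical-name window merge, and
#' plural split. Character offsets are preserved throughout: every token's
#' surface equals the source slice at its range, and interleaving token
#' surfaces with the skipped slices reconstructs the document exactly.
#'
#' @param text document string.
#' @param docId document identifier.
#' @param entities entity-surface \code{\linkS4class{Lexicon}} (step-2 gate
#'   and rule-5 base lookup).
#' @param affixes domain-affix \code{\linkS4class{Lexicon}} (step 2.1).
#' @param chemNames known-chemical-name \code{\linkS4class{Lexicon}}
#'   (rules 4 and 5).
#' @param config a \code{\linkS4class{TokenizerConfig}}.
#' @return a \code{\linkS4class{TokenSequence}}.
#' @examples
#' chem <- Lexicon("Acid", ignoreCase = TRUE)
#' tokenSurfaces(tokenize("(1-3) Common Acids", chemNames = chem))
#' @export
tokenize <- function(text, docId = "doc", entities = Lexicon(),
                     affixes = Lexicon(), chemNames = Lexicon(),
                     config = tokenizerConfig()) {
    seq <- splitWhitespace(text, docId)
    seq <- splitAffixes(seq, affixes)
    seq <- splitDelimiters(seq, entities, config)
    if (config@rule1) seq <- mergeNumericRuns(seq, config)
    if (config@rule2) seq <- mergeBalancedContainers(seq, config)
    if (config@rule3) seq <- mergeSingleUppercase(seq)
    if (config@rule4) seq <- mergeKnownNames(seq, chemNames, config)
    if (config@rule5) seq <- splitPluralForms(seq, entities, chemNames,
                                              config)
    seq
}

#' Whitespace baseline tokenizer
#'
#' The generic baseline used in segmentation-quality comparisons: identical
#' to \code{\link{splitWhitespace}}, exposed under a registry name.
#'
#' @inheritParams splitWhitespace
#' @return a \code{\linkS4class{TokenSequence}}.
#' @export
tokenizeWhitespace <- function(text, docId = "doc")
    splitWhitespace(text, docId)

#' Pure case-change splitting baseline
#'
#' A negative-control tokenizer that splits at whitespace and then at every
#' adjacent pair of letters with differing case, with no repair rules. On
#' text such as "CONCLUSIONGlucose" it produces "CONCLUSIONG" + "lucose",
#' the failure mode the rule pipeline's repair rules exist to avoid.
#'
#' @inheritParams splitWhitespace
#' @return a \code{\linkS4class{TokenSequence}}.
#' @export
tokenizeCaseSplit <- function(text, docId = "doc") {
    seq <- splitWhitespace(text, docId)
    n <- length(seq@ranges)
    if (n == 0L) return(seq)
    s <- IRanges::start(seq@ranges); e <- IRanges::end(seq@ranges)
    surf <- tokenSurfaces(seq)
    ns <- integer(0); ne <- integer(0)
    for (i in seq_len(n)) {
        chars <- strsplit(surf[i], "", fixed = TRUE)[[1L]]
        cat <- .charCategories(chars)
        m <- length(chars)
        if (m == 1L) {
            ns <- c(ns, s[i]); ne <- c(ne, e[i])
            next
        }
        a <- cat[-m]; b <- cat[-1L]
        cut <- (a == "U" & b == "L") | (a == "L" & b == "U")
        bounds <- c(0L, which(cut), m)
        ns <- c(ns, s[i] + bounds[-length(bounds)])
        ne <- c(ne, s[i] + bounds[-1L] - 1L)
    }
    .tokenSeq(seq@docId, seq@sourceText, ns, ne)
}

#' Look up a tokenizer by registry name
#'
#' @param name one of \code{"rules"}, \code{"whitespace"},
#'   \code{"casesplit"}.
#' @return a function \code{(text, docId, ...)} returning a
#'   \code{\linkS4class{TokenSequence}}; \code{"rules"} accepts the lexicon
#'   and config arguments of \code{\link{tokenize}}.
#' @export
getTokenizer <- function(name = c("rules", "whitespace", "casesplit")) {
    name <- match.arg(name)
    switch(name,
           rules = tokenize,
           whitespace = tokenizeWhitespace,
           casesplit = tokenizeCaseSplit)
}

#' Reconstruct the source text from a TokenSequence
#'
#' Interleaves token surfaces with the skipped inter-token slices of the
#' source. Used to assert the round-trip invariant.
#'
#' @param seq a \code{\linkS4class{TokenSequence}}.
#' @return the reconstructed document string; equal to
#'   \code{sourceText(seq)} for any sequence produced by the tokenizers.
#' @export
reconstructText <- function(seq) {
    stopifnot(is(seq, "TokenSequence"))
    txt <- seq@sourceText
    n <- length(seq@ranges)
    if (n == 0L) return(txt)
    s <- IRanges::start(seq@ranges); e <- IRanges::end(seq@ranges)
    pieces <- character(0)
    pieces <- c(pieces, substr(txt, 1L, s[1L] - 1L))
    for (i in seq_len(n)) {
        pieces <- c(pieces, substring(txt, s[i], e[i]))
        gapEnd <- if (i < n) s[i + 1L] - 1L else nchar(txt)
        pieces <- c(pieces, substring(txt, e[i] + 1L, gapEnd))
    }
    paste(pieces, collapse = "")
}
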