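#' @import methods
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors isSorted
NULL

#' Lexicon: a set of surface strings with a case policy
#'
#' A \code{Lexicon} holds one of the word lists the tokenizer consults:
#' domain affixes, known entity surface forms, known chemical names, or
#' plural suffixes. Membership queries respect the lexicon's case policy.
#'
#' @slot entries character vector of unique, non-empty entries (no newlines).
#' @slot ignoreCase logical; if \code{TRUE}, membership is case-insensitive
#'   and entries are deduplicated after case folding.
#' @slot name a short label used in logs and \code{show()}.
#'
#' @seealso \code{\link{readLexicon}}, \code{\link{lexiconContains}},
#'   \code{\link{findPrefixAffix}}
#' @exportClass Lexicon
setClass("Lexicon",
    representation(entries = "character", ignoreCase = "logical",
                   name = "character"),
    prototype(entries = character(0), ignoreCase = FALSE, name = "lexicon"))

setValidity("Lexicon", function(object) {
    msg <- character(0)
    if (length(object@ignoreCase) != 1L || is.na(object@ignoreCase))
        msg <- c(msg, "'ignoreCase' must be TRUE or FALSE")
    if (length(object@name) != 1L)
        msg <- c(msg, "'name' must be a single string")
    e <- object@entries
    if (anyNA(e) || any(!nzchar(e)))
        msg <- c(msg, "entries must be non-empty and non-NA")
    if (any(grepl("[\r\n]", e)))
        msg <- c(msg, "entries must not contain newlines")
    key <- if (isTRUE(object@ignoreCase)) tolower(e) else e
    if (anyDuplicated(key))
        msg <- c(msg, "entries must be unique under the case policy")
    if (length(msg)) msg else TRUE
})

#' TokenizerConfig: tunable behaviour of the rule tokenizer
#'
#' Collects every switch of the segmentation pipeline: which merge rules run,
#' the separator and container sets they use, the sliding-window size of the
#' known-name merge, the plural suffixes, and the case policy of the entity
#' gate. Construct with \code{\link{tokenizerConfig}}.
#'
#' @slot caseSplit logical; split at letter case changes (step 2).
#' @slot rule1,rule2,rule3,rule4,rule5 logical toggles for the five
#'   merge/repair rules of step 3.
#' @slot rule4Window integer window size (>= 2) of the known-name merge.
#' @slot separators single characters joining numeric tokens (rule 1).
#' @slot openers,closers matched container pairs (rule 2), position-aligned.
#' @slot pluralSuffixes suffixes tried, in order, by the plurality rule.
#' @slot entityGateIgnoreCase logical; case policy of the entity-lexicon gate
#'   applied before delimiter splitting.
#' @exportClass TokenizerConfig
setClass("TokenizerConfig",
    representation(caseSplit = "logical",
                   rule1 = "logical", rule2 = "logical", rule3 = "logical",
                   rule4 = "logical", rule5 = "logical",
                   rule4Window = "integer",
                   separators = "character",
                   openers = "character", closers = "character",
                   pluralSuffixes = "character",
                   entityGateIgnoreCase = "logical"))

setValidity("TokenizerConfig", function(object) {
    msg <- character(0)
    for (s in c("caseSplit", "rule1", "rule2", "rule3", "rule4", "rule5",
                "entityGateIgnoreCase")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v))
            msg <- c(msg, sprintf("'%s' must be TRUE or FALSE", s))
    }
    if (length(object@rule4Window) != 1L || is.na(object@rule4Window) ||
        object@rule4Window < 2L)
        msg <- c(msg, "'rule4Window' must be a single integer >= 2")
    if (isTRUE(object@rule1) && length(object@separators) == 0L)
        msg <- c(msg, "'separators' must be non-empty when rule 1 is enabled")
    if (any(nchar(object@separators) != 1L))
        msg <- c(msg, "'separators' must be single characters")
    if (length(object@openers) != length(object@closers))
        msg <- c(msg, "'openers' and 'closers' must be position-aligned")
    if (isTRUE(object@rule2) && length(object@openers) == 0L)
        msg <- c(msg, "container pairs must be non-empty when rule 2 is enabled")
    if (isTRUE(object@rule5) && length(object@pluralSuffixes) == 0L)
        msg <- c(msg, "'pluralSuffixes' must be non-empty when rule 5 is enabled")
    if (length(msg)) msg else TRUE
})

#' TokenSequence: offset-anchored tokens over one document
#'
#' The central container of the package: an ordered set of whitespace-free
#' tokens anchored to the character coordinates of their source document.
#' Token positions are stored as an \code{IRanges} in 1-based closed
#' coordinates over the document string; the accessors
#' \code{\link{tokenStarts}} and \code{\link{tokenEnds}} expose the 0-based
#' half-open convention used by the annotation files.
#'
#' The class maintains the round-trip invariant: re-inserting the skipped
#' source slices between the token surfaces reconstructs the document
#' exactly, because each surface \emph{is} the source slice at its range.
#'
#' @slot docId document identifier.
#' @slot sourceText the full document text the offsets index into.
#' @slot ranges an \code{IRanges} of token positions, strictly increasing
#'   and non-overlapping; no token spans whitespace.
#' @exportClass TokenSequence
setClass("TokenSequence",
    representation(docId = "character", sourceText = "character",
                   ranges = "IRanges"))

setValidity("TokenSequence", function(object) {
    msg <- character(0)
    if (length(object@docId) != 1L || is.na(object@docId))
        msg <- c(msg, "'docId' must be a single string")
    if (length(object@sourceText) != 1L || is.na(object@sourceText))
        msg <- c(msg, "'sourceText' must be a single string")
    r <- object@ranges
    n <- length(r)
    if (n > 0L) {
        s <- IRanges::start(r); e <- IRanges::end(r)
        if (any(e < s))
            msg <- c(msg, "token ranges must have positive width")
        if (s[1L] < 1L || e[n] > nchar(object@sourceText))
            msg <- c(msg, "token ranges must lie within the source text")
        if (n > 1L && any(s[-1L] <= e[-n]))
            msg <- c(msg, "token ranges must be strictly increasing and disjoint")
        surf <- substring(object@sourceText, s, e)
        if (any(grepl("[[:space:]]", surf)))
            msg <- c(msg, "token surfaces must not contain whitespace")
    }
    if (length(msg)) msg else TRUE
})
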