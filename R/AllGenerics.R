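#' Accessors for TokenSequence objects
#'
#' \code{tokenSurfaces} returns the token strings; \code{tokenRanges} the
#' underlying \code{IRanges} (1-based closed); \code{tokenStarts} and
#' \code{tokenEnds} the 0-based half-open offsets used by the annotation
#' file dialect; \code{docId} and \code{sourceText} the document identity
#' and text; \code{nTokens} the number of tokens.
#'
#' @param x a \code{\linkS4class{TokenSequence}}.
#' @return \code{tokenSurfaces}: character vector; \code{tokenRanges}:
#'   \code{IRanges}; \code{tokenStarts}/\code{tokenEnds}: integer vectors;
#'   \code{docId}/\code{sourceText}: single strings; \code{nTokens}: integer.
#' @examples
#' ts <- splitWhitespace("tetrazolium bromide", "d1")
#' tokenSurfaces(ts)
#' tokenStarts(ts)  # 0-based half-open
#' @name TokenSequence-accessors
#' @aliases tokenSurfaces tokenRanges tokenStarts tokenEnds docId sourceText
#'   nTokens
NULL

#' @rdname TokenSequence-accessors
#' @export
setGeneric("tokenSurfaces", function(x) standardGeneric("tokenSurfaces"))

#' @rdname TokenSequence-accessors
#' @export
setGeneric("tokenRanges", function(x) standardGeneric("tokenRanges"))

#' @rdname TokenSequence-accessors
#' @export
setGeneric("tokenStarts", function(x) standardGeneric("tokenStarts"))

#' @rdname TokenSequence-accessors
#' @export
setGeneric("tokenEnds", function(x) standardGeneric("tokenEnds"))

#' @rdname TokenSequence-accessors
#' @export
setGeneric("docId", function(x) standardGeneric("docId"))

#' @rdname TokenSequence-accessors
#' @export
setGeneric("sourceText", function(x) standardGeneric("sourceText"))

#' @rdname TokenSequence-accessors
#' @export
setGeneric("nTokens", function(x) standardGeneric("nTokens"))

#' Query lexicon membership
#'
#' @param lex a \code{\linkS4class{Lexicon}}.
#' @param s character vector of strings to look up.
#' @param ignoreCase override of the lexicon's case policy (optional).
#' @return logical vector, one element per string in \code{s}. The empty
#'   string is never a member.
#' @examples
#' lx <- Lexicon(c("NaCl", "cisplatin"), ignoreCase = TRUE)
#' lexiconContains(lx, c("NACL", "water"))
#' @export
setGeneric("lexiconContains",
    function(lex, s, ignoreCase = NULL) standardGeneric("lexiconContains"))

#' @rdname lexiconContains
#' @param x a \code{Lexicon}.
#' @export
setGeneric("lexiconEntries", function(x) standardGeneric("lexiconEntries"))
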