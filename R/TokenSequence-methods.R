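## Internal constructor: starts/ends are 1-based closed character positions.
.tokenSeq <- function(docId, text, starts, ends) {
    new("TokenSequence", docId = as.character(docId),
        sourceText = as.character(text),
        ranges = IRanges::IRanges(start = as.integer(starts),
                                  end = as.integer(ends)))
}

#' @rdname TokenSequence-accessors
#' @export
setMethod("tokenSurfaces", "TokenSequence", function(x) {
    if (length(x@ranges) == 0L) return(character(0))
    substring(x@sourceText, IRanges::start(x@ranges),
              IRanges::end(x@ranges))
})

#' @rdname TokenSequence-accessors
#' @export
setMethod("tokenRanges", "TokenSequence", function(x) x@ranges)

#' @rdname TokenSequence-accessors
#' @export
setMethod("tokenStarts", "TokenSequence", function(x)
    IRanges::start(x@ranges) - 1L)

#' @rdname TokenSequence-accessors
#' @export
setMethod("tokenEnds", "TokenSequence", function(x) IRanges::end(x@ranges))

#' @rdname TokenSequence-accessors
#' @export
setMethod("docId", "TokenSequence", function(x) x@docId)

#' @rdname TokenSequence-accessors
#' @export
setMethod("sourceText", "TokenSequence", function(x) x@sourceText)

#' @rdname TokenSequence-accessors
#' @export
setMethod("nTokens", "TokenSequence", function(x) length(x@ranges))

#' @rdname TokenSequence-accessors
#' @export
setMethod("length", "TokenSequence", function(x) length(x@ranges))

#' @param object a \code{TokenSequence}.
#' @rdname TokenSequence-accessors
#' @export
setMethod("show", "TokenSequence", function(object) {
    n <- length(object@ranges)
    cat(sprintf("TokenSequence '%s': %d token%s over %d characters\n",
                object@docId, n, if (n == 1L) "" else "s",
                nchar(object@sourceText)))
    if (n) {
        surf <- tokenSurfaces(object)
        shown <- utils::head(surf, 8L)
        cat("  ", paste(shown, collapse = " | "),
            if (n > 8L) " | ..." else "", "\n", sep = "")
    }
})

#' Convert a TokenSequence to a data.frame
#'
#' Columns \code{docId}, \code{start}, \code{end} (0-based half-open, the
#' annotation file convention) and \code{surface}.
#'
#' @param x a \code{\linkS4class{TokenSequence}}.
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @return a \code{data.frame} with one row per token.
#' @method as.data.frame TokenSequence
#' @export
as.data.frame.TokenSequence <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
    data.frame(docId = rep(x@docId, length(x@ranges)),
               start = tokenStarts(x), end = tokenEnds(x),
               surface = tokenSurfaces(x), stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "TokenSequence",
          function(x, ...) as.data.frame.TokenSequence(x, ...))
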