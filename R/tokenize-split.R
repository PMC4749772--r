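## Character classes used throughout the package:
##   U  ASCII uppercase letter      L  ASCII lowercase letter
##   D  digit                       G  non-ASCII letter (Greek etc.)
##   P  everything else (punctuation/symbols; tokens never hold whitespace)
.charCategories <- function(chars) {
    cp <- vapply(chars, function(ch) utf8ToInt(ch)[1L], integer(1),
                 USE.NAMES = FALSE)
    cat <- rep("P", length(chars))
    cat[cp >= 48L & cp <= 57L] <- "D"            # 0-9
    cat[cp >= 65L & cp <= 90L] <- "U"            # A-Z
    cat[cp >= 97L & cp <= 122L] <- "L"           # a-z
    other <- cat == "P" & stringi::stri_detect_regex(chars, "^\\p{L}$")
    cat[other] <- "G"
    cat
}

#' Split raw text at whitespace
#'
#' Step 1 of the segmentation algorithm: every maximal run of non-whitespace
#' characters becomes a token, with exact character offsets into the source.
#'
#' @param text a document string (NFC-normalized on entry).
#' @param docId document identifier.
#' @return a \code{\linkS4class{TokenSequence}}.
#' @examples
#' splitWhitespace("tetrazolium bromide", "d1")
#' @export
splitWhitespace <- function(text, docId = "doc") {
    text <- stringi::stri_trans_nfc(as.character(text))
    if (is.na(text)) text <- ""
    m <- gregexpr("[^[:space:]]+", text)[[1L]]
    if (length(m) == 1L && m[1L] == -1L)
        return(.tokenSeq(docId, text, integer(0), integer(0)))
    starts <- as.integer(m)
    ends <- starts + attr(m, "match.length") - 1L
    .tokenSeq(docId, text, starts, ends)
}

#' Split tokens at known domain-affix boundaries
#'
#' Step 2.1: each token carrying a known affix as a proper prefix (per
#' \code{\link{findPrefixAffix}}) is replaced by two adjacent tokens that
#' partition its offsets — e.g. "hyperinsulinaemia" becomes "hyper" +
#' "insulinaemia". Tokens without a matching affix pass through unchanged.
#'
#' @param seq a \code{\linkS4class{TokenSequence}}.
#' @param affixes affix \code{\linkS4class{Lexicon}}.
#' @return a \code{TokenSequence} with the same coverage.
#' @examples
#' af <- Lexicon(c("Hyper", "Anti", "Amino"), ignoreCase = TRUE)
#' tokenSurfaces(splitAffixes(splitWhitespace("Antiherpetic agent"), af))
#' @export
splitAffixes <- function(seq, affixes) {
    stopifnot(is(seq, "TokenSequence"), is(affixes, "Lexicon"))
    if (length(seq@ranges) == 0L || length(affixes@entries) == 0L)
        return(seq)
    s <- IRanges::start(seq@ranges); e <- IRanges::end(seq@ranges)
    surf <- tokenSurfaces(seq)
    ns <- integer(0); ne <- integer(0)
    for (i in seq_along(surf)) {
        pos <- findPrefixAffix(surf[i], affixes)
        if (is.na(pos)) {
            ns <- c(ns, s[i]); ne <- c(ne, e[i])
        } else {
            ns <- c(ns, s[i], s[i] + pos)
            ne <- c(ne, s[i] + pos - 1L, e[i])
        }
    }
    .tokenSeq(seq@docId, seq@sourceText, ns, ne)
}

## Split one token (given as char categories) into relative segments.
## Returns integer matrix with columns rs, re (1-based, relative).
## Cut points, between positions i and i+1:
##   - either side is P or G (those characters stand alone),
##   - digit-run boundary (exactly one side is D),
##   - letter case change (U|L or L|U),
##   - inside an uppercase run whose next letter is lowercase (U U L):
##     the run's last uppercase letter is detached so that the repair rule
##     can rebuild the embedded capitalized word ("...IONGlucose" ->
##     "...ION" "G" "lucose").
.delimiterCuts <- function(cat) {
    n <- length(cat)
    if (n == 1L) return(logical(0))
    a <- cat[-n]; b <- cat[-1L]
    cut <- a == "P" | b == "P" | a == "G" | b == "G" |
        xor(a == "D", b == "D") |
        (a == "U" & b == "L") | (a == "L" & b == "U")
    if (n > 2L) {
        uul <- which(cat[-c(n - 1L, n)] == "U" & cat[-c(1L, n)] == "U" &
                     cat[-c(1L, 2L)] == "L")
        cut[uul] <- TRUE
    }
    cut
}

.splitTokenAtDelimiters <- function(surface, caseSplit = TRUE) {
    chars <- strsplit(surface, "", fixed = TRUE)[[1L]]
    cat <- .charCategories(chars)
    n <- length(chars)
    if (n == 1L) return(cbind(rs = 1L, re = 1L))
    cut <- .delimiterCuts(cat)
    if (!caseSplit) {
        a <- cat[-n]; b <- cat[-1L]
        keep <- a == "P" | b == "P" | a == "G" | b == "G" |
            xor(a == "D", b == "D")
        cut <- cut & keep
    }
    bounds <- c(0L, which(cut), n)
    rs <- bounds[-length(bounds)] + 1L
    re <- bounds[-1L]
    cbind(rs = rs, re = re)
}

#' Split tokens at delimiters, digit runs, Greek letters and case changes
#'
#' Step 2.2: tokens found verbatim in the entity lexicon are assumed to be
#' correctly bounded and pass through untouched (the "entity gate"). Every
#' other token is partitioned so that each punctuation character and each
#' non-ASCII letter stands alone, maximal digit runs form single tokens, and
#' letters are cut at case changes. An uppercase run followed by lowercase
#' additionally detaches its final uppercase letter, so that the single
#' uppercase + lowercase repair rule can rebuild an embedded capitalized
#' word (e.g. "CONCLUSIONGlucose" yields "CONCLUSION", "G", "lucose").
#'
#' @param seq a \code{\linkS4class{TokenSequence}}.
#' @param entities entity-surface \code{\linkS4class{Lexicon}} (the gate).
#' @param config a \code{\linkS4class{TokenizerConfig}}.
#' @return a \code{TokenSequence}.
#' @examples
#' lx <- Lexicon("d-alpha-tocopheryl-co-poly")
#' tokenSurfaces(splitDelimiters(
#'     splitWhitespace("d-alpha-tocopheryl-co-poly here"), lx))
#' @export
splitDelimiters <- function(seq, entities = Lexicon(),
                            config = tokenizerConfig()) {
    stopifnot(is(seq, "TokenSequence"), is(entities, "Lexicon"),
              is(config, "TokenizerConfig"))
    if (length(seq@ranges) == 0L) return(seq)
    s <- IRanges::start(seq@ranges); e <- IRanges::end(seq@ranges)
    surf <- tokenSurfaces(seq)
    gated <- lexiconContains(entities, surf,
                             ignoreCase = config@entityGateIgnoreCase)
    ns <- integer(0); ne <- integer(0)
    for (i in seq_along(surf)) {
        if (gated[i]) {
            ns <- c(ns, s[i]); ne <- c(ne, e[i])
        } else {
            seg <- .splitTokenAtDelimiters(surf[i], config@caseSplit)
            ns <- c(ns, s[i] + seg[, "rs"] - 1L)
            ne <- c(ne, s[i] + seg[, "re"] - 1L)
        }
    }
    .tokenSeq(seq@docId, seq@sourceText, ns, ne)
}
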