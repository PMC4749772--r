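#' Construct a Lexicon from a character vector
#'
#' Entries are NFC-normalized and whitespace-trimmed; blank entries are
#' dropped and duplicates (after case folding when \code{ignoreCase}) are
#' collapsed, keeping the first occurrence.
#'
#' @param entries character vector of surface strings.
#' @param ignoreCase logical; case-insensitive membership if \code{TRUE}.
#' @param name label used in logs and printing.
#' @return a \code{\linkS4class{Lexicon}}.
#' @examples
#' Lexicon(c("Hyper", "Anti", "Amino"), ignoreCase = TRUE, name = "affixes")
#' @export
Lexicon <- function(entries = character(0), ignoreCase = FALSE,
                    name = "lexicon") {
    entries <- stringi::stri_trans_nfc(as.character(entries))
    entries <- trimws(entries)
    entries <- entries[nzchar(entries)]
    key <- if (ignoreCase) tolower(entries) else entries
    entries <- entries[!duplicated(key)]
    new("Lexicon", entries = entries, ignoreCase = ignoreCase, name = name)
}

#' Load a lexicon from a one-entry-per-line text file
#'
#' The file is UTF-8 plain text with one entry per line; blank lines and
#' lines starting with \code{#} are skipped, surrounding whitespace is
#' stripped and duplicates are collapsed under the case policy.
#'
#' @param path path to the lexicon file.
#' @inheritParams Lexicon
#' @return a \code{\linkS4class{Lexicon}}. An empty result is valid but
#'   raises a warning.
#' @examples
#' f <- tempfile()
#' writeLines(c("Hyper", "# a comment", "", "Anti", "Amino"), f)
#' readLexicon(f, ignoreCase = TRUE, name = "affixes")
#' @export
readLexicon <- function(path, ignoreCase = FALSE, name = basename(path)) {
    if (!file.exists(path))
        stop("lexicon file not found: ", path, call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    lex <- Lexicon(lines, ignoreCase = ignoreCase, name = name)
    if (length(lex@entries) == 0L)
        warning("lexicon '", name, "' is empty after filtering", call. = FALSE)
    lex
}

#' Write a lexicon to a one-entry-per-line text file
#'
#' @param lex a \code{\linkS4class{Lexicon}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLexicon <- function(lex, path) {
    stopifnot(is(lex, "Lexicon"))
    writeLines(lex@entries, path, useBytes = FALSE)
    invisible(path)
}

#' @rdname lexiconContains
setMethod("lexiconContains", "Lexicon", function(lex, s, ignoreCase = NULL) {
    ic <- if (is.null(ignoreCase)) lex@ignoreCase else isTRUE(ignoreCase)
    s <- as.character(s)
    out <- if (ic) tolower(s) %in% tolower(lex@entries) else s %in% lex@entries
    out & nzchar(s) & !is.na(s)
})

#' @rdname lexiconContains
setMethod("lexiconEntries", "Lexicon", function(x) x@entries)

#' @param object a \code{Lexicon}.
#' @rdname lexiconContains
#' @export
setMethod("show", "Lexicon", function(object) {
    cat(sprintf("Lexicon '%s': %d entries (%s)\n", object@name,
                length(object@entries),
                if (object@ignoreCase) "case-insensitive" else "case-sensitive"))
    if (length(object@entries)) {
        head <- utils::head(object@entries, 5L)
        cat("  ", paste(head, collapse = ", "),
            if (length(object@entries) > 5L) ", ..." else "", "\n", sep = "")
    }
})

#' @rdname lexiconContains
#' @export
setMethod("length", "Lexicon", function(x) length(x@entries))

#' Find the longest domain affix prefixing a token
#'
#' Searches the affix lexicon, case-insensitively, for entries matching at
#' position 0 of \code{token}. Returns the number of characters of the
#' longest such affix, provided a non-empty remainder follows; otherwise
#' \code{NA}. The returned value is the split position: the token is divided
#' into \code{[0, pos)} and \code{[pos, n)}.
#'
#' Affix matching is prefix-only and a token is split at most once: the
#' motivating conjoined forms ("Aminoacid", "hyperinsulinaemia",
#' "Antiherpetic") all carry the affix in initial position, and restricting
#' to prefixes avoids shredding ordinary words on internal substrings.
#'
#' @param token a non-empty string.
#' @param affixes a \code{\linkS4class{Lexicon}} of domain affixes.
#' @return integer split position, or \code{NA_integer_} if no affix applies.
#' @examples
#' af <- Lexicon(c("Hyper", "Anti", "Amino"), ignoreCase = TRUE)
#' findPrefixAffix("hyperinsulinaemia", af)  # 5
#' findPrefixAffix("Hyper", af)              # NA: empty remainder
#' @export
findPrefixAffix <- function(token, affixes) {
    stopifnot(is.character(token), length(token) == 1L, nzchar(token),
              is(affixes, "Lexicon"))
    ents <- affixes@entries
    if (!length(ents)) return(NA_integer_)
    tl <- tolower(token)
    w <- nchar(ents)
    hit <- w < nchar(token) & startsWith(tl, tolower(ents))
    if (!any(hit)) return(NA_integer_)
    max(w[hit])
}
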