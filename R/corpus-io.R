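## File dialects (documented here and in the vignette):
##   abstracts TSV:   doc_id <TAB> title <TAB> abstract. The stored document
##                    text is title and abstract joined by a single tab, so
##                    annotation offsets index the concatenated record.
##   annotation TSV:  doc_id <TAB> section (T|A|-) <TAB> start <TAB> end
##                    <TAB> surface <TAB> class; offsets are 0-based
##                    half-open into the stored document text.
##   CoNLL-style:     "# doc <id>" header, then surface <TAB> start <TAB>
##                    end <TAB> label per token, blank line between docs.

.readLinesUtf8 <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    stringi::stri_trans_nfc(readLines(path, encoding = "UTF-8",
                                      warn = FALSE))
}

#' Read a corpus of abstracts
#'
#' TSV dialect: \code{doc_id TAB title TAB abstract}, one document per
#' line. The record text is the title and abstract joined by a single tab
#' character, preserved so that annotation offsets index the concatenated
#' record. Malformed lines raise an error naming the line number (or are
#' skipped with a message when \code{strict = FALSE}); duplicate document
#' ids are always an error.
#'
#' @param path path to the abstracts TSV.
#' @param strict fail on malformed lines (default) instead of skipping.
#' @return a \code{data.frame} with columns \code{docId}, \code{text}.
#' @export
readAbstracts <- function(path, strict = TRUE) {
    lines <- .readLinesUtf8(path)
    lines <- lines[nzchar(lines)]
    ids <- character(0); texts <- character(0)
    for (ln in seq_along(lines)) {
        parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
        if (length(parts) != 3L) {
            if (strict)
                stop(sprintf("malformed abstracts line %d: expected 3 fields, got %d",
                             ln, length(parts)), call. = FALSE)
            message("skipping malformed abstracts line ", ln)
            next
        }
        ids <- c(ids, parts[1L])
        texts <- c(texts, paste(parts[2L], parts[3L], sep = "\t"))
    }
    if (anyDuplicated(ids))
        stop("duplicate doc_id in abstracts file: ",
             ids[duplicated(ids)][1L], call. = FALSE)
    data.frame(docId = ids, text = texts, stringsAsFactors = FALSE)
}

#' Write a corpus of abstracts
#'
#' Inverse of \code{\link{readAbstracts}}: each record's text must contain
#' the single tab separating title from abstract.
#'
#' @param documents \code{data.frame} with columns \code{docId},
#'   \code{text}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAbstracts <- function(documents, path) {
    stopifnot(is.data.frame(documents),
              all(c("docId", "text") %in% names(documents)))
    writeLines(paste(documents$docId, documents$text, sep = "\t"), path,
               useBytes = FALSE)
    invisible(path)
}

#' Read gold entity annotations
#'
#' Six-column TSV: \code{doc_id}, \code{section} (\code{T}, \code{A} or
#' \code{-}), \code{start}, \code{end} (0-based half-open into the stored
#' record text), \code{surface}, \code{class}. When \code{documents} is
#' supplied, offsets are checked against document bounds and the surface
#' against the text slice; violations raise an error naming the document
#' and row.
#'
#' @param path path to the annotation TSV.
#' @param documents optional abstracts \code{data.frame} (from
#'   \code{\link{readAbstracts}}) for bounds/surface validation.
#' @param strict fail on malformed rows (default) instead of skipping.
#' @return an entity-span \code{data.frame} (see
#'   \code{\link{emptyEntityFrame}}) with an extra \code{section} column.
#' @export
readAnnotations <- function(path, documents = NULL, strict = TRUE) {
    lines <- .readLinesUtf8(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    out <- emptyEntityFrame()
    out$section <- character(0)
    rows <- list()
    for (ln in seq_along(lines)) {
        parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
        bad <- NULL
        if (length(parts) != 6L) {
            bad <- sprintf("expected 6 fields, got %d", length(parts))
        } else {
            start <- suppressWarnings(as.integer(parts[3L]))
            end <- suppressWarnings(as.integer(parts[4L]))
            if (is.na(start) || is.na(end)) bad <- "non-integer offsets"
            else if (start < 0L) bad <- "negative offset"
            else if (end <= start) bad <- "end <= start"
        }
        if (is.null(bad) && !is.null(documents)) {
            hit <- match(parts[1L], documents$docId)
            if (is.na(hit)) bad <- "unknown doc_id"
            else if (end > nchar(documents$text[hit]))
                bad <- "offsets beyond document bounds"
            else {
                slice <- substr(documents$text[hit], start + 1L, end)
                if (slice != parts[5L])
                    bad <- sprintf("surface mismatch: file '%s' vs text '%s'",
                                   parts[5L], slice)
            }
        }
        if (!is.null(bad)) {
            msg <- sprintf("annotation row %d (doc '%s'): %s", ln,
                           if (length(parts)) parts[1L] else "?", bad)
            if (strict) stop(msg, call. = FALSE)
            message("skipping ", msg)
            next
        }
        rows[[length(rows) + 1L]] <- data.frame(
            docId = parts[1L], start = start, end = end,
            surface = parts[5L], entityClass = parts[6L],
            section = parts[2L], stringsAsFactors = FALSE)
    }
    if (length(rows)) out <- do.call(rbind, rows)
    out
}

#' Write gold entity annotations
#'
#' @param entities entity-span \code{data.frame}; an optional
#'   \code{section} column is written, else \code{-}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(entities, path) {
    .checkEntityFrame(entities)
    section <- if ("section" %in% names(entities)) entities$section
               else rep("-", nrow(entities))
    lines <- paste(entities$docId, section, entities$start, entities$end,
                   entities$surface, entities$entityClass, sep = "\t")
    writeLines(lines, path, useBytes = FALSE)
    invisible(path)
}

#' Write tokens as a four-column TSV
#'
#' One token per line: \code{doc_id}, \code{start}, \code{end} (0-based
#' half-open), \code{surface}.
#'
#' @param seqs a list of \code{\linkS4class{TokenSequence}} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTokens <- function(seqs, path) {
    stopifnot(is.list(seqs))
    dfs <- lapply(seqs, as.data.frame)
    df <- do.call(rbind, c(dfs, list(make.row.names = FALSE)))
    lines <- if (is.null(df) || !nrow(df)) character(0)
             else paste(df$docId, df$start, df$end, df$surface, sep = "\t")
    writeLines(lines, path, useBytes = FALSE)
    invisible(path)
}

#' Write / read labeled tokens in CoNLL style
#'
#' Each document starts with a \code{# doc <id>} header, followed by one
#' token per line (\code{surface TAB start TAB end TAB label}) and a blank
#' line. \code{readConll} inverts \code{writeConll} exactly.
#'
#' @param labeled a \code{data.frame} with columns \code{docId},
#'   \code{start}, \code{end}, \code{surface}, \code{label} (the
#'   \code{tokens} element of \code{\link{alignAndLabel}}), possibly
#'   covering several documents.
#' @param path output (input) path.
#' @return \code{writeConll}: \code{path}, invisibly; \code{readConll}:
#'   the labeled-token \code{data.frame}.
#' @export
writeConll <- function(labeled, path) {
    stopifnot(is.data.frame(labeled),
              all(c("docId", "start", "end", "surface", "label") %in%
                  names(labeled)))
    lines <- character(0)
    for (id in unique(labeled$docId)) {
        d <- labeled[labeled$docId == id, , drop = FALSE]
        lines <- c(lines, paste("# doc", id),
                   paste(d$surface, d$start, d$end, d$label, sep = "\t"),
                   "")
    }
    writeLines(lines, path, useBytes = FALSE)
    invisible(path)
}

#' @rdname writeConll
#' @export
readConll <- function(path) {
    lines <- .readLinesUtf8(path)
    cur <- NA_character_
    rows <- list()
    for (ln in seq_along(lines)) {
        line <- lines[ln]
        if (!nzchar(line)) next
        if (startsWith(line, "# doc ")) {
            cur <- substring(line, 7L)
            next
        }
        if (is.na(cur))
            stop("CoNLL line ", ln, " appears before any '# doc' header",
                 call. = FALSE)
        parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
        if (length(parts) != 4L)
            stop("malformed CoNLL line ", ln, call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
            docId = cur, start = as.integer(parts[2L]),
            end = as.integer(parts[3L]), surface = parts[1L],
            label = parts[4L], stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(docId = character(0), start = integer(0),
                          end = integer(0), surface = character(0),
                          label = character(0), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
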