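#' Tokenize every document of a corpus
#'
#' @param documents abstracts \code{data.frame} (\code{docId},
#'   \code{text}).
#' @param tokenizer registry name (see \code{\link{getTokenizer}}).
#' @param lexica list with elements \code{entities}, \code{affixes},
#'   \code{chemNames} (\code{\linkS4class{Lexicon}} objects); only used by
#'   the \code{"rules"} tokenizer.
#' @param config a \code{\linkS4class{TokenizerConfig}}.
#' @return a list of \code{\linkS4class{TokenSequence}}, one per document.
#' @export
tokenizeCorpus <- function(documents, tokenizer = "rules",
                           lexica = list(entities = Lexicon(),
                                         affixes = Lexicon(),
                                         chemNames = Lexicon()),
                           config = tokenizerConfig()) {
    stopifnot(is.data.frame(documents),
              all(c("docId", "text") %in% names(documents)))
    fn <- getTokenizer(tokenizer)
    lapply(seq_len(nrow(documents)), function(i) {
        if (identical(tokenizer, "rules"))
            fn(documents$text[i], documents$docId[i],
               entities = lexica$entities, affixes = lexica$affixes,
               chemNames = lexica$chemNames, config = config)
        else
            fn(documents$text[i], documents$docId[i])
    })
}

#' Compare tokenizers on an annotated corpus
#'
#' Runs each named tokenizer over the corpus and reports NT (token count),
#' ATL (average token length in characters) and NISE (number of
#' incorrectly segmented entities) per tokenizer, one row each.
#'
#' @inheritParams tokenizeCorpus
#' @param annotations gold entity-span \code{data.frame}.
#' @param tokenizers character vector of registry names.
#' @return a \code{data.frame} with one row per tokenizer.
#' @examples
#' syn <- generateCorpus(7, nDocs = 5)
#' evaluateTokenizers(syn$documents, syn$annotations, syn$lexica)
#' @export
evaluateTokenizers <- function(documents, annotations,
                               lexica = list(entities = Lexicon(),
                                             affixes = Lexicon(),
                                             chemNames = Lexicon()),
                               tokenizers = c("rules", "whitespace"),
                               config = tokenizerConfig()) {
    rows <- lapply(tokenizers, function(tk) {
        seqs <- tokenizeCorpus(documents, tk, lexica, config)
        computeStats(seqs, annotations, tk)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
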