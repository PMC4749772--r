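#' Create a tokenizer configuration
#'
#' Defaults reproduce the published rule set: numeric tokens joined by
#' \code{. , / - _} are re-merged (rule 1); balanced \code{() [] {}} around
#' a numeric chain are absorbed (rule 2); a single uppercase letter rejoins
#' a following lowercase token (rule 3); concatenations of up to five
#' consecutive tokens found in the known-chemical-name list merge, searched
#' case-insensitively (rule 4); and plural tokens whose base form is a known
#' entity or chemical name split into base + suffix, suffixes tried in the
#' order \code{ies}, \code{es}, \code{s} (rule 5).
#'
#' @param caseSplit split tokens at letter case changes (default \code{TRUE}).
#' @param rule1,rule2,rule3,rule4,rule5 enable the individual merge rules.
#' @param rule4Window sliding-window size of the known-name merge (>= 2).
#' @param separators single-character separators for the numeric merge.
#' @param openers,closers aligned container pairs for rule 2.
#' @param pluralSuffixes plural suffixes, tried in order, for rule 5.
#' @param entityGateIgnoreCase case policy of the entity-lexicon gate;
#'   \code{FALSE} by default because chemical abbreviations such as "TPGS"
#'   are case-significant.
#' @return a validated \code{\linkS4class{TokenizerConfig}}.
#' @examples
#' tokenizerConfig()
#' tokenizerConfig(rule5 = FALSE)
#' @export
tokenizerConfig <- function(caseSplit = TRUE,
                            rule1 = TRUE, rule2 = TRUE, rule3 = TRUE,
                            rule4 = TRUE, rule5 = TRUE,
                            rule4Window = 5L,
                            separators = c(".", ",", "/", "-", "_"),
                            openers = c("(", "[", "{"),
                            closers = c(")", "]", "}"),
                            pluralSuffixes = c("ies", "es", "s"),
                            entityGateIgnoreCase = FALSE) {
    new("TokenizerConfig",
        caseSplit = caseSplit,
        rule1 = rule1, rule2 = rule2, rule3 = rule3, rule4 = rule4,
        rule5 = rule5,
        rule4Window = as.integer(rule4Window),
        separators = separators, openers = openers, closers = closers,
        pluralSuffixes = pluralSuffixes,
        entityGateIgnoreCase = entityGateIgnoreCase)
}

#' Read a tokenizer configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{tokenizerConfig}}; absent keys
#' keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a \code{\linkS4class{TokenizerConfig}}.
#' @export
readTokenizerConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path, call. = FALSE)
    vals <- yaml::read_yaml(path)
    known <- names(formals(tokenizerConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config keys: ", paste(bad, collapse = ", "),
             call. = FALSE)
    do.call(tokenizerConfig, vals)
}

#' @param object a \code{TokenizerConfig}.
#' @rdname tokenizerConfig
#' @export
setMethod("show", "TokenizerConfig", function(object) {
    on <- c("1", "2", "3", "4", "5")[c(object@rule1, object@rule2,
                                       object@rule3, object@rule4,
                                       object@rule5)]
    cat("TokenizerConfig\n",
        "  caseSplit: ", object@caseSplit, "\n",
        "  rules enabled: ", if (length(on)) paste(on, collapse = ",")
                             else "none", "\n",
        "  rule4Window: ", object@rule4Window, "\n",
        "  separators: ", paste(object@separators, collapse = " "), "\n",
        "  containers: ",
        paste(paste0(object@openers, object@closers), collapse = " "), "\n",
        "  pluralSuffixes: ", paste(object@pluralSuffixes, collapse = ","),
        "\n",
        "  entityGateIgnoreCase: ", object@entityGateIgnoreCase, "\n",
        sep = "")
})
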