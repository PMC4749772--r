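# Independent brute-force oracles for the step-3 merge rules. These
# enumerate candidate merges from the rule definitions directly (window
# enumeration / recursion) instead of the package's single-pass scans, so
# agreement is a genuine two-route check.

.tokFrame <- function(seq) {
    data.frame(surface = tokenSurfaces(seq), start = tokenStarts(seq),
               end = tokenEnds(seq), stringsAsFactors = FALSE)
}

.mergeRows <- function(df, i, j, text) {
    s <- df$start[i]; e <- df$end[j]
    merged <- data.frame(surface = substr(text, s + 1L, e),
                         start = s, end = e, stringsAsFactors = FALSE)
    rbind(if (i > 1L) df[1:(i - 1L), ] else NULL, merged,
          if (j < nrow(df)) df[(j + 1L):nrow(df), ] else NULL)
}

oracleIsNum <- function(s) grepl("^[0-9]+$", s)
oracleIsChain <- function(s, seps) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    d <- grepl("^[0-9]$", ch); p <- ch %in% seps
    length(ch) > 0L && d[1L] && d[length(ch)] && all(d | p) &&
        !any(!d[-length(ch)] & !d[-1L])
}

# Rule 1 oracle: enumerate every window [i, j]; a legal chain window
# alternates numeric / single-char separator, starts and ends numeric, and
# is source-contiguous. Merge exactly the maximal legal windows.
oracleRule1 <- function(seq, seps = c(".", ",", "/", "-", "_")) {
    df <- .tokFrame(seq)
    n <- nrow(df)
    legal <- function(i, j) {
        if ((j - i) %% 2L != 0L || j > n) return(FALSE)
        idx <- i:j
        num <- oracleIsNum(df$surface[idx])
        sep <- nchar(df$surface[idx]) == 1L & df$surface[idx] %in% seps
        alt <- all(num[seq(1L, length(idx), 2L)]) &&
            (length(idx) == 1L || all(sep[seq(2L, length(idx), 2L)]))
        contig <- all(df$end[i:(j - 1L)] == df$start[(i + 1L):j])
        alt && contig
    }
    windows <- list()
    for (i in seq_len(n)) for (j in if (i + 2L > n) integer(0)
                                    else seq(i + 2L, n, by = 2L)) {
        if (legal(i, j) &&
            !(i > 2L && legal(i - 2L, j)) &&
            !(j + 2L <= n && legal(i, j + 2L)))
            windows[[length(windows) + 1L]] <- c(i, j)
    }
    for (w in rev(windows))
        df <- .mergeRows(df, w[1L], w[2L], sourceText(seq))
    df
}

# Rule 2 oracle: enumerate all triples (opener, numeric chain, matching
# closer), all source-contiguous, and merge them.
oracleRule2 <- function(df, text, seps = c(".", ",", "/", "-", "_"),
                        op = c("(", "[", "{"), cl = c(")", "]", "}")) {
    repeat {
        n <- nrow(df)
        hit <- NULL
        for (i in seq_len(max(0L, n - 2L))) {
            oi <- match(df$surface[i], op)
            ci <- match(df$surface[i + 2L], cl)
            if (!is.na(oi) && !is.na(ci) && oi == ci &&
                oracleIsChain(df$surface[i + 1L], seps) &&
                df$end[i] == df$start[i + 1L] &&
                df$end[i + 1L] == df$start[i + 2L]) {
                hit <- i
                break
            }
        }
        if (is.null(hit)) return(df)
        df <- .mergeRows(df, hit, hit + 2L, text)
    }
}

# Rule 3 oracle: recursively merge the leftmost single-uppercase +
# all-lowercase contiguous pair; recursion resumes after the merged token.
oracleRule3 <- function(df, text, from = 1L) {
    n <- nrow(df)
    i <- from
    while (i < n) {
        if (grepl("^[A-Z]$", df$surface[i]) &&
            grepl("^[a-z]+$", df$surface[i + 1L]) &&
            df$end[i] == df$start[i + 1L]) {
            df <- .mergeRows(df, i, i + 1L, text)
            return(oracleRule3(df, text, from = i + 1L))
        }
        i <- i + 1L
    }
    df
}

# Rule 4 oracle: at each position (left to right) enumerate all window
# lengths window..2 and take the longest whose contiguous concatenation is
# a known name (case-insensitive); recurse after any merge.
oracleRule4 <- function(df, text, known, window = 5L, from = 1L) {
    knownLower <- tolower(known)
    n <- nrow(df)
    for (i in seq(from, length.out = max(0L, n - from + 1L))) {
        wmax <- min(window, n - i + 1L)
        if (wmax < 2L) next
        for (w in rev(seq(2L, wmax))) {
            j <- i + w - 1L
            if (!all(df$end[i:(j - 1L)] == df$start[(i + 1L):j])) next
            if (tolower(paste(df$surface[i:j], collapse = "")) %in%
                knownLower) {
                df <- .mergeRows(df, i, j, text)
                return(oracleRule4(df, text, known, window, from = i + 1L))
            }
        }
    }
    df
}

# Exhaustive prefix-affix scan used as the lexicon-module oracle.
oracleFindPrefixAffix <- function(token, affixEntries) {
    best <- NA_integer_
    for (a in affixEntries) {
        k <- nchar(a)
        if (k < nchar(token) &&
            tolower(substr(token, 1L, k)) == tolower(a) &&
            (is.na(best) || k > best))
            best <- k
    }
    best
}

# Random test strings over a small mixed alphabet (letters of both cases,
# digits, separators, containers, spaces).
randomString <- function(maxLen = 30L) {
    alphabet <- c("a", "b", "c", "A", "B", "C", "1", "2", "3",
                  "(", ")", "[", "]", "-", ",", ".", "/", " ", " ")
    n <- sample.int(maxLen + 1L, 1L) - 1L
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Small lexica reused across tests.
paperAffixes <- function() Lexicon(c("Hyper", "Anti", "Amino"),
                                   ignoreCase = TRUE, name = "affixes")
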