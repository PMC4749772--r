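test_that("the full pipeline composes the three steps and five rules", {
    chem <- Lexicon("Acid", ignoreCase = TRUE)
    expect_identical(tokenSurfaces(tokenize("(1-3) Common Acids",
                                            chemNames = chem)),
                     c("(1-3)", "Common", "Acid", "s"))
    expect_identical(nTokens(tokenize("")), 0L)

    ent <- Lexicon(c("3-(4,5-dimethylthiazol-2-yl)-2,5-diphenyl",
                     "tetrazolium", "bromide"))
    out <- tokenize(paste("reduce",
                          "3-(4,5-dimethylthiazol-2-yl)-2,5-diphenyl",
                          "tetrazolium bromide (MTT)"), entities = ent)
    expect_true(all(c("3-(4,5-dimethylthiazol-2-yl)-2,5-diphenyl",
                      "tetrazolium", "bromide") %in% tokenSurfaces(out)))
})

test_that("pipeline equals the explicit composition of its stages", {
    set.seed(31)
    af <- paperAffixes()
    ent <- Lexicon(c("a-1", "Bc"))
    chem <- Lexicon(c("aB", "b1b"), ignoreCase = TRUE)
    cfg <- tokenizerConfig()
    for (k in 1:50) {
        x <- randomString(30L)
        direct <- tokenize(x, "d", ent, af, chem, cfg)
        staged <- splitWhitespace(x, "d")
        staged <- splitAffixes(staged, af)
        staged <- splitDelimiters(staged, ent, cfg)
        staged <- mergeNumericRuns(staged, cfg)
        staged <- mergeBalancedContainers(staged, cfg)
        staged <- mergeSingleUppercase(staged)
        staged <- mergeKnownNames(staged, chem, cfg)
        staged <- splitPluralForms(staged, ent, chem, cfg)
        expect_identical(as.data.frame(direct), as.data.frame(staged))
    }
})

test_that("round-trip reconstruction holds for every tokenizer on random
           input", {
    set.seed(57)
    chem <- Lexicon(c("aB", "ab1"), ignoreCase = TRUE)
    for (k in 1:200) {
        x <- randomString(30L)
        for (mk in list(tokenize(x, chemNames = chem),
                        tokenizeWhitespace(x), tokenizeCaseSplit(x))) {
            expect_identical(reconstructText(mk),
                             stringi::stri_trans_nfc(x))
            s <- tokenStarts(mk); e <- tokenEnds(mk)
            expect_true(all(e > s))
            if (length(s) > 1L) expect_true(all(s[-1L] >= e[-length(e)]))
            expect_false(any(grepl("\\s", tokenSurfaces(mk))))
        }
    }
})

test_that("tokenization is deterministic", {
    chem <- Lexicon("NaCL", ignoreCase = TRUE)
    x <- "NaCL (1-3) CONCLUSIONGlucose 12,5 mg/kg"
    expect_identical(as.data.frame(tokenize(x, chemNames = chem)),
                     as.data.frame(tokenize(x, chemNames = chem)))
})

test_that("adding an entity to the gate never increases its token count", {
    set.seed(73)
    for (k in 1:100) {
        x <- randomString(12L)
        x <- gsub("\\s", "", x)
        if (!nzchar(x)) next
        without <- nTokens(tokenize(x))
        with <- nTokens(tokenize(x, entities = Lexicon(x)))
        expect_lte(with, without)
    }
})

test_that("merged tokens never span whitespace in the source", {
    set.seed(91)
    chem <- Lexicon(c("aB", "a1", "BA"), ignoreCase = TRUE)
    for (k in 1:100) {
        x <- randomString(30L)
        tk <- tokenize(x, chemNames = chem)
        expect_false(any(grepl("\\s", tokenSurfaces(tk))))
    }
})

test_that("the whitespace baseline matches plain whitespace splitting", {
    x <- "  d-alpha-tocopheryl-co-poly(ethylene glycol) 1000 succinate "
    expect_identical(as.data.frame(tokenizeWhitespace(x, "d")),
                     as.data.frame(splitWhitespace(x, "d")))
    expect_identical(getTokenizer("whitespace"), tokenizeWhitespace)
    expect_error(getTokenizer("unregistered"))
})

test_that("the case-split baseline reproduces the documented failure mode", {
    out <- tokenizeCaseSplit("CONCLUSIONGlucose")
    expect_identical(tokenSurfaces(out), c("CONCLUSIONG", "lucose"))
})
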