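# Build a post-step-2 sequence from raw text for merge-rule tests.
step2 <- function(text, entities = Lexicon(), affixes = Lexicon(),
                  cfg = tokenizerConfig())
    splitDelimiters(splitAffixes(splitWhitespace(text), affixes),
                    entities, cfg)

test_that("rule 1 merges separator-joined numeric chains", {
    out <- mergeNumericRuns(step2("125,12,12"))
    expect_identical(tokenSurfaces(out), "125,12,12")
    expect_identical(tokenSurfaces(mergeNumericRuns(step2("1-3"))), "1-3")
    # non-numeric operand blocks the merge
    expect_identical(tokenSurfaces(mergeNumericRuns(step2("12,ab"))),
                     c("12", ",", "ab"))
    # merges never cross whitespace
    expect_identical(tokenSurfaces(mergeNumericRuns(step2("12 , 12"))),
                     c("12", ",", "12"))
})

test_that("rule 2 absorbs balanced containers around numeric chains", {
    r12 <- function(x) mergeBalancedContainers(mergeNumericRuns(step2(x)))
    expect_identical(tokenSurfaces(r12("(1-3)")), "(1-3)")
    expect_identical(tokenSurfaces(r12("[42]")), "[42]")
    expect_identical(tokenSurfaces(r12("{7}")), "{7}")
    # mismatched pair is not balanced
    expect_identical(tokenSurfaces(r12("(1-3]")), c("(", "1-3", "]"))
    # containers around alphabetic content stay split
    expect_identical(tokenSurfaces(r12("(ab)")), c("(", "ab", ")"))
})

test_that("rule 2 merge set matches brute force over container pairs and
           numeric contents", {
    for (op in c("(", "[", "{")) for (inner in c("1", "1-3", "12,5"))
        for (cl in c(")", "]", "}")) {
            x <- paste0(op, inner, cl)
            r1 <- mergeNumericRuns(step2(x))
            got <- tokenSurfaces(mergeBalancedContainers(r1))
            orc <- oracleRule2(.tokFrame(r1), sourceText(r1))$surface
            expect_identical(got, orc)
        }
})

test_that("rule 3 rejoins a single uppercase letter to following lowercase", {
    expect_identical(tokenSurfaces(mergeSingleUppercase(step2("Common"))),
                     "Common")
    # left token longer than one letter does not merge
    ab <- mergeSingleUppercase(step2("ABcd"))
    expect_false("ABcd" %in% tokenSurfaces(ab))
    # pairwise, left to right
    expect_identical(
        tokenSurfaces(mergeSingleUppercase(step2("CommonSense"))),
        c("Common", "Sense"))
    # never across whitespace
    expect_identical(
        tokenSurfaces(mergeSingleUppercase(step2("B activation"))),
        c("B", "activation"))
})

test_that("rule 4 merges known chemical names over a sliding window", {
    chem <- Lexicon(c("NaCL", "H2O"), ignoreCase = TRUE)
    r3 <- function(x) mergeSingleUppercase(step2(x))
    expect_identical(tokenSurfaces(mergeKnownNames(r3("NaCL"), chem)),
                     "NaCL")
    expect_identical(tokenSurfaces(mergeKnownNames(r3("H2O"), chem)),
                     "H2O")
    # case-insensitive search
    expect_identical(tokenSurfaces(mergeKnownNames(r3("nacl"),
                                                   Lexicon("NaCL"))),
                     "nacl")
    # empty lexicon: no merges
    expect_identical(tokenSurfaces(mergeKnownNames(r3("NaCL"), Lexicon())),
                     tokenSurfaces(r3("NaCL")))
})

test_that("rule 4 window merges 2-5 contiguous subtokens and never 6+", {
    # "a1" repeated k/2 times splits into k alternating subtokens
    for (k in c(2L, 3L, 4L, 5L)) {
        word <- paste(rep(c("a", "1"), length.out = k), collapse = "")
        chem <- Lexicon(word, ignoreCase = TRUE)
        out <- mergeKnownNames(step2(word), chem)
        expect_identical(tokenSurfaces(out), word)
    }
    for (k in c(6L, 7L)) {
        word <- paste(rep(c("a", "1"), length.out = k), collapse = "")
        chem <- Lexicon(word, ignoreCase = TRUE)
        out <- mergeKnownNames(step2(word), chem)
        expect_identical(nTokens(out), k)
    }
})

test_that("rule 5 splits plural tokens whose base is a known name", {
    chem <- Lexicon(c("salicylate", "Acid", "clonidine"),
                    ignoreCase = TRUE)
    out <- splitPluralForms(step2("salicylates"), chemNames = chem)
    expect_identical(tokenSurfaces(out), c("salicylate", "s"))
    out2 <- splitPluralForms(mergeSingleUppercase(step2("Acids")),
                             chemNames = chem)
    expect_identical(tokenSurfaces(out2), c("Acid", "s"))
    # suffix order: ies, es, s; raw strip without base restoration
    out3 <- splitPluralForms(step2("clonidines"), chemNames = chem)
    expect_identical(tokenSurfaces(out3), c("clonidine", "s"))
    # lexicon gate blocks ordinary English
    expect_identical(tokenSurfaces(splitPluralForms(step2("is"),
                                                    chemNames = chem)),
                     "is")
    # entity lexicon also gates the split
    out4 <- splitPluralForms(step2("cisplatins"),
                             entities = Lexicon("cisplatin"))
    expect_identical(tokenSurfaces(out4), c("cisplatin", "s"))
})

test_that("rules 1-4 agree with brute-force merge enumeration on random
           strings", {
    set.seed(202)
    known <- c("aB", "ab1", "BA", "b1b", "A1a", "ca-1b")
    chem <- Lexicon(known, ignoreCase = TRUE)
    cfg <- tokenizerConfig()
    for (k in 1:300) {
        x <- randomString(30L)
        s2 <- step2(x)
        got <- mergeKnownNames(
            mergeSingleUppercase(
                mergeBalancedContainers(
                    mergeNumericRuns(s2, cfg), cfg)), chem, cfg)
        df <- oracleRule1(s2)
        df <- oracleRule2(df, sourceText(s2))
        df <- oracleRule3(df, sourceText(s2))
        df <- oracleRule4(df, sourceText(s2), known)
        expect_identical(tokenSurfaces(got), df$surface)
        expect_identical(tokenStarts(got), df$start)
        expect_identical(tokenEnds(got), df$end)
    }
})
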