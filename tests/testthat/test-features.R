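test_that("the feature vector has exactly 25 features in 7 fixed groups", {
    expect_length(featureNames(), 25L)
    grp <- featureGroups()
    expect_identical(as.integer(table(factor(grp,
        levels = c("space", "context", "ngram_affix", "word_shape",
                   "orthographic", "length", "chem_affix")))),
        c(3L, 2L, 8L, 3L, 7L, 1L, 1L))

    ts <- tokenize("reduce NaCL (1-3) doses", "d1")
    for (i in seq_len(nTokens(ts))) {
        fv <- extractFeatures(ts, i, paperAffixes())
        expect_length(fv, 25L)
        expect_identical(names(fv), featureNames())
        expect_identical(attr(fv, "groups"), featureGroups())
    }
    expect_error(extractFeatures(ts, 99L), "out of range")
})

test_that("space features read the source characters and document
           boundaries count as space", {
    ts <- splitWhitespace("a b c")
    expect_identical(unname(spaceFeatures(ts, 2L)), c(TRUE, TRUE, TRUE))
    ts2 <- splitDelimiters(splitWhitespace("x(y"))
    expect_identical(unname(spaceFeatures(ts2, 2L)),
                     c(FALSE, FALSE, FALSE))
    # merged "(1-3)" inside "a(1-3)" has "(" flush left
    ts3 <- tokenize("a(1-3)")
    i <- match("(1-3)", tokenSurfaces(ts3))
    expect_false(spaceFeatures(ts3, i)[["has_left_space"]])
    expect_true(spaceFeatures(ts3, i)[["has_right_space"]])
})

test_that("context words use the PAD sentinel at boundaries", {
    ts <- tokenize("NF-kappa", "d1")
    expect_identical(unname(contextWords(ts, 2L)), c("NF", "kappa"))
    expect_identical(contextWords(ts, 1L)[["prev_token"]], "<PAD>")
    single <- tokenize("one")
    expect_identical(unname(contextWords(single, 1L)),
                     c("<PAD>", "<PAD>"))
})

test_that("n-gram affixes cover lengths 1-4 with whole-surface fallback", {
    expect_identical(unname(ngramAffixes("acid")),
                     c("a", "ac", "aci", "acid", "d", "id", "cid", "acid"))
    expect_identical(unname(ngramAffixes("Na")),
                     c("N", "Na", "Na", "Na", "a", "Na", "Na", "Na"))
})

test_that("word shapes serialize counts, per-character classes and
           collapsed runs", {
    sh <- wordShapes("NaCL")
    expect_identical(sh[["word_shape"]], "U:3|L:1|D:0|P:0|G:0")
    expect_identical(sh[["digital_shape"]], "AaAA")
    expect_identical(sh[["summarized_shape"]], "AaA")
    expect_identical(wordShapes("(1-3)")[["digital_shape"]], "p0p0p")
    expect_identical(wordShapes("aaaa")[["summarized_shape"]], "a")
    expect_identical(wordShapes("aβ2")[["digital_shape"]], "ag0")
})

test_that("orthographic features match their definitions", {
    mtt <- orthographicFeatures("MTT")
    expect_true(mtt[["all_uppercase"]])
    expect_true(mtt[["more_than_2_uppercase"]])
    expect_false(mtt[["has_punctuation"]])
    expect_false(mtt[["has_real_number"]])

    frag <- orthographicFeatures("3-(4,5")
    expect_true(frag[["has_punctuation"]])
    expect_true(frag[["starts_with_digit"]])
    expect_false(frag[["all_uppercase"]])

    expect_true(orthographicFeatures("mg/kg")[["has_slash"]])
    expect_true(orthographicFeatures("Na")[["starts_with_uppercase"]])
    expect_false(orthographicFeatures("Na")[["more_than_2_uppercase"]])
})

test_that("chemical-affix flag scans prefixes and suffixes
           case-insensitively", {
    expect_true(chemAffixFlag("hyperplasia", Lexicon("hyper")))
    expect_true(chemAffixFlag("chloride", Lexicon("ide")))
    expect_true(chemAffixFlag("Hyperplasia", Lexicon("hyper")))
    expect_false(chemAffixFlag("water", Lexicon("hyper")))
    expect_false(chemAffixFlag("water", Lexicon()))
})

test_that("feature extraction is deterministic and label-blind", {
    ts <- tokenize("NaCL here", chemNames = Lexicon("NaCL"))
    fv1 <- extractFeatures(ts, 1L)
    fv2 <- extractFeatures(ts, 1L)
    expect_identical(fv1, fv2)
    expect_identical(fv1[["token_length"]], 4L)
    expect_identical(fv1[["digital_shape"]], "AaAA")
    expect_false("label" %in% names(fv1))
})

test_that("feature tables round-trip through the TSV export", {
    ts <- tokenize("reduce NaCL (1-3) doses now", "d1",
                   chemNames = Lexicon("NaCL"))
    tab <- featureTable(ts, paperAffixes(),
                        labels = rep("O", nTokens(ts)))
    expect_identical(nrow(tab), nTokens(ts))
    f <- withr::local_tempfile()
    writeFeatures(tab, f)
    back <- readFeatures(f)
    expect_identical(back, tab)
})
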