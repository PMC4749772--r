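test_that("corpus generation is deterministic given the seed", {
    a <- generateCorpus(42, nDocs = 10)
    b <- generateCorpus(42, nDocs = 10)
    expect_identical(a, b)
    c <- generateCorpus(43, nDocs = 10)
    expect_false(identical(a$documents, c$documents))
})

test_that("every generated gold span matches its text slice", {
    syn <- generateCorpus(17, nDocs = 20)
    txt <- syn$documents$text[match(syn$manifest$docId,
                                    syn$documents$docId)]
    slice <- substr(txt, syn$manifest$start + 1L, syn$manifest$end)
    expect_identical(slice, syn$manifest$surface)
    expect_true(all(syn$manifest$kind %in% phenomenonKinds()))
})

test_that("single-phenomenon corpora contain only that phenomenon", {
    w <- c(plural_form = 1)
    syn <- generateCorpus(8, nDocs = 5, weights = w)
    expect_true(all(syn$manifest$kind == "plural_form"))
    # every gold entity is the singular inside a plural surface form
    txt <- syn$documents$text[match(syn$manifest$docId,
                                    syn$documents$docId)]
    after <- substr(txt, syn$manifest$end + 1L, syn$manifest$end + 2L)
    expect_true(all(substr(after, 1L, 1L) == "s" |
                    substr(after, 1L, 2L) == "es"))
    expect_true(all(lexiconContains(syn$lexica$chemNames,
                                    syn$manifest$surface)))

    cf <- generateCorpus(8, nDocs = 5, weights = c(case_fused = 1))
    expect_true(all(cf$manifest$kind == "case_fused"))
    # gold span starts mid-word, right after an uppercase header
    txtCf <- cf$documents$text[match(cf$manifest$docId,
                                     cf$documents$docId)]
    before <- substr(txtCf, cf$manifest$start, cf$manifest$start)
    expect_true(all(grepl("^[A-Z]$", before)))
})

test_that("expected violations: baseline counts boundary-fusing phenomena,
           rules count zero", {
    syn <- generateCorpus(21, nDocs = 15)
    m <- syn$manifest
    fusing <- c("hyphen_conjoined", "paren_formula", "plural_form",
                "affix_containment", "case_fused")
    expect_identical(expectedViolations(m, "whitespace"),
                     sum(m$kind %in% fusing))
    expect_identical(expectedViolations(m, "rules"), 0L)
    expect_identical(expectedViolations(m[0, ], "whitespace"), 0L)
    expect_error(expectedViolations(m, "unregistered"), "unknown tokenizer")
})

test_that("measured NISE equals the manifest oracle for both tokenizers", {
    syn <- generateCorpus(99, nDocs = 25)
    st <- evaluateTokenizers(syn$documents, syn$annotations, syn$lexica,
                             c("rules", "whitespace"))
    expect_identical(st$NISE[st$tokenizer == "rules"],
                     expectedViolations(syn$manifest, "rules"))
    expect_identical(st$NISE[st$tokenizer == "whitespace"],
                     expectedViolations(syn$manifest, "whitespace"))
    expect_lte(st$NISE[st$tokenizer == "rules"],
               st$NISE[st$tokenizer == "whitespace"])
})

test_that("generated corpora write to disk in the supported formats", {
    syn <- generateCorpus(4, nDocs = 3)
    dir <- withr::local_tempdir()
    writeCorpus(syn, dir)
    expect_true(all(file.exists(file.path(dir,
        c("abstracts.tsv", "annotations.tsv", "entities.txt",
          "affixes.txt", "chem_names.txt", "manifest.json")))))
    docs <- readAbstracts(file.path(dir, "abstracts.tsv"))
    expect_identical(docs, syn$documents)
    ann <- readAnnotations(file.path(dir, "annotations.tsv"), docs)
    expect_identical(ann[, names(syn$annotations)], syn$annotations)
})

test_that("generator inputs are validated", {
    expect_error(generateCorpus(1, weights = c(bogus = 1)), "weights")
    expect_error(generateCorpus(1, weights = c(plural_form = 0)),
                 "positive sum")
    empty <- generateCorpus(1, nDocs = 0)
    expect_identical(nrow(empty$documents), 0L)
    expect_identical(nrow(empty$manifest), 0L)
})
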