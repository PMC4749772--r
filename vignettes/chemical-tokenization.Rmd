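---
title: "Rule-based tokenization for chemical named-entity recognition"
author: "ChemSeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based tokenization for chemical named-entity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChemSeg)
```

## The problem

Sequence-labeling NER systems (CRFs, SVMs) see text only through the
tokenizer that precedes them. A classifier can recover an entity mention
only if the mention's boundaries coincide with token boundaries; a gold
span that starts or ends strictly inside a token is unlearnable, however
good the classifier. Chemical text breaks naive tokenizers in systematic
ways:

* entity names fused to neighbouring text by hyphens
  (`TPGS-cisplatin`: two entities in one whitespace token) or directly to
  uppercase headers (`CONCLUSIONGlucose`);
* internal punctuation and digits that must *not* be split
  (`d-alpha-tocopheryl-co-poly`) next to identical characters that must
  (`poly(ethylene glycol)`);
* numeric formulas wrapped in containers (`(1-3)`) glued to adjacent
  words;
* plural surface forms (`salicylates`) annotated as their singular;
* entities embedded in longer words behind a productive affix
  (`hyperinsulinaemia`).

ChemSeg implements an offset-preserving, rule-based tokenizer that first
over-splits aggressively and then merges tokens back with a small set of
repair rules, aiming at the longest tokens that do not violate entity
boundaries. It also provides the evaluation side: IOB labeling against
gold character-offset spans, the segmentation metrics NT (number of
tokens), ATL (average token length) and NISE (number of incorrectly
segmented entities), a 25-feature extractor for downstream classifiers,
and a seeded generator of synthetic corpora exhibiting each phenomenon
above.

## The segmentation algorithm

Every token is anchored to half-open character offsets of its document (an
`IRanges` internally), so each surface *is* the source slice at its range
and interleaving tokens with the skipped slices reconstructs the document
byte for byte. All steps preserve this invariant; merges only ever join
source-contiguous tokens, so no token can acquire whitespace.

**Step 1 — whitespace split.** Maximal runs of non-whitespace characters
become tokens.

**Step 2.1 — affix split.** A token carrying a known domain affix
(`hyper`, `anti`, `amino`, ...) as a proper prefix is divided at the affix
boundary: `hyperinsulinaemia` → `hyper` + `insulinaemia`. Matching is
case-insensitive, prefix-only, longest-affix-first, and at most one split
per token. Prefix-only is a deliberate narrowing: all motivating conjoined
forms carry the affix initially, and infix matching would shred ordinary
vocabulary.

**Step 2.2 — entity gate and delimiter split.** A token found verbatim in
the entity lexicon (surface forms collected from training annotations) is
assumed correctly bounded and passes untouched — this is what keeps
`d-alpha-tocopheryl-co-poly` whole. The gate is case-sensitive by default
(`TPGS` ≠ `tpgs`), switchable in the configuration. Every other token is
partitioned so that

* each punctuation character and each non-ASCII letter (Greek etc.)
  stands alone,
* maximal digit runs form single tokens (`125` stays whole; the split is
  at digit/non-digit boundaries, not per digit),
* letters are cut at every adjacent case change (both `aB` and `Ba`
  boundaries), and
* an uppercase run followed by lowercase additionally detaches its final
  uppercase letter: `CONCLUSIONGlucose` → `CONCLUSION` + `G` + `lucose`.

The last clause is the package's resolution of a genuinely open design
point. Case-change splitting alone yields `CONCLUSIONG` + `lucose`, from
which no local merge rule can rebuild `Glucose` — that is precisely the
failure mode of a pure case splitter, reproduced here by
`tokenizeCaseSplit()` as a negative control. Detaching the run's last
capital makes the over-split uniform (`Common` → `C` + `ommon`,
`...IONGlucose` → `...ION` + `G` + `lucose`) and leaves exactly one repair
rule responsible for rebuilding capitalized words.

**Step 3 — merge rules.** Applied in order, one left-to-right pass each
(no fixpoint iteration; every motivating example resolves in one pass):

1. *Numeric chains.* Alternating numeric / single-separator tokens
   (`. , / - _`) merge: `125 , 12 , 12` → `125,12,12`.
2. *Balanced containers.* An opening container, a numeric chain, and the
   matching closer merge: `( 1-3 )` → `(1-3)`. Restricted to numeric
   content; wrapping arbitrary parenthesised words would re-fuse
   `poly(ethylene` style text the splitter just fixed.
3. *Single uppercase + lowercase.* `C` + `ommon` → `Common`,
   `G` + `lucose` → `Glucose`.
4. *Known names.* A sliding window of up to 5 consecutive
   source-contiguous tokens is searched case-insensitively against a
   known-chemical-name list; hits merge greedily, longest window first,
   leftmost first (maximizing token length, the design objective):
   `Na` + `CL` → `NaCL`.
5. *Plurality.* A token ending in `ies`, `es` or `s` (tried in that
   order) whose raw-stripped base is a known entity or chemical name
   splits into base + suffix: `salicylates` → `salicylate` + `s`. The
   lexicon gate is essential — ungated, the rule would split `is` and
   `its`. The `ies` suffix is stripped raw (no `y` restoration) so the
   two tokens partition the original surface and offsets stay exact.

`tokenize()` composes all steps; each step is also exported for
inspection and ablation (`splitWhitespace()`, `splitAffixes()`,
`splitDelimiters()`, `mergeNumericRuns()`, `mergeBalancedContainers()`,
`mergeSingleUppercase()`, `mergeKnownNames()`, `splitPluralForms()`).

```{r}
chem <- Lexicon(c("NaCL", "Acid"), ignoreCase = TRUE)
tokenSurfaces(tokenize("(1-3) Common Acids and NaCL", chemNames = chem))
```

## Alignment, labels and metrics

`alignAndLabel()` operationalizes "incorrectly segmented": an entity is
correct iff some token starts at its start offset, some token ends at its
end offset, and every overlapping token lies wholly inside the span. This
is the strictest reading of boundary violation; anything looser would
credit tokenizations a classifier cannot exploit. Correct entities yield
`B-<class>`/`I-<class>` labels; violating entities are returned in a
violation table and their interior tokens stay `O` — a sequence model
cannot learn a partial span, so emitting fragmentary labels would
manufacture noise. Overlapping gold spans are rejected rather than
resolved. Each annotation row counts independently in NISE.

`computeStats()` and `evaluateTokenizers()` aggregate NT, ATL and NISE
per tokenizer over a corpus.

```{r}
ts <- tokenize("inhibition of NF-kappa B activation", "d1")
gold <- data.frame(docId = "d1", start = 14, end = 24,
                   surface = "NF-kappa B", entityClass = "CHEMICAL")
alignAndLabel(ts, gold)$tokens[, c("surface", "label")]
```

## The feature scheme

`extractFeatures()` emits exactly 25 features in 7 groups per token:
3 space features (whitespace right / left / both, document boundaries
counting as space), 2 context words (±1 token, `<PAD>` at boundaries —
the window is deliberately not widened), 8 n-gram affixes (prefixes and
suffixes, n = 1..4; shorter surfaces repeat the whole surface rather than
padding, keeping values readable), 3 word shapes, 7 orthographic
booleans, token length, and a chemical-affix flag (affix occurs
case-insensitively as prefix or suffix).

Two shape features have no standard definition, so the package fixes one
for reproducibility: the *digital shape* maps each character to its class
over the alphabet `A` (uppercase), `a` (lowercase), `0` (digit), `p`
(punctuation), `g` (other letter), and the *summarized shape* collapses
runs of equal classes (`NaCL` → `AaAA` → `AaA`). "Has real number" is
defined as containing a digit run optionally with one decimal point.
Feature extraction never sees labels, and `writeFeatures()` /
`readFeatures()` round-trip the table exactly (logicals serialized as
`1`/`0`) for export to sequence-labeling toolkits.

## The synthetic corpus generator

Real chemical NER corpora are large, licensed, and unnecessary for
verifying segmentation logic. `generateCorpus(seed, nDocs)` builds
documents from fixed template vocabularies — filler words, lowercase drug
stems, uppercase abbreviations, section headers, affix+stem compounds —
so that each sampled phenomenon plants a gold span whose correctness
under each tokenizer is known by construction:

* `hyphen_conjoined`, `paren_formula`, `plural_form`,
  `affix_containment` and `case_fused` all place an entity boundary
  strictly inside a whitespace token, so the whitespace baseline provably
  violates them, while the rule pipeline (run with the lexica the
  generator returns) repairs every one;
* `internal_space_entity` and `simple_entity` boundaries coincide with
  whitespace boundaries, so both tokenizers handle them.

`expectedViolations()` turns the manifest into an exact NISE oracle for
both tokenizers; the test suite checks measured NISE against it. For the
affix-containment phenomenon the generated gold span is the full
remainder after the affix (`insulinaemia` in `hyperinsulinaemia`): the
affix split can restore exactly that boundary, whereas a shorter embedded
annotation (such as `insulin`) is unreachable by any boundary-preserving
tokenizer and is documented as a known limitation, not generated.

What the generator does *not* emulate: realistic language statistics,
corpus-scale token counts, annotation noise, overlapping or discontinuous
mentions, and sentence structure. Passing tests therefore demonstrate the
segmentation logic and metrics, not corpus-level performance on real
abstracts.

## Numerical and degenerate-input choices

* All user-facing offsets are 0-based half-open (the annotation file
  convention); internally ranges are 1-based closed `IRanges`. Readers
  and writers convert at the boundary.
* Input text and lexica are NFC-normalized on read; no further Unicode
  folding (confusables are out of scope).
* Character classes are decided on code points, not locale collation.
* Empty documents yield empty token sequences; empty lexica are valid
  (with a warning on load) and simply disable their rules.
* The tokenizer has no randomness and no global state; configuration and
  lexica are the only inputs besides the text.
* Default problem sizes in tests and the acceptance script — 100
  synthetic documents, 1000 random strings of length ≤ 30 for the
  brute-force merge-oracle comparison — were chosen as the smallest sizes
  at which every phenomenon and rule interaction is exercised many times
  over.

## Known limitations

* Affix splitting is prefix-only and non-recursive; entities embedded
  behind two stacked affixes, or annotated strictly inside the affix
  remainder, are not recovered.
* Rule 2 wraps containers around numeric chains only; parenthesized
  alphabetic formula fragments rely on the entity gate instead.
* The entity gate is consulted once, before delimiter splitting; tokens
  created by step-3 merges are not re-checked against it.
* The supported annotation import is the offsets-TSV dialect; XML corpus
  distributions need conversion to it first.
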