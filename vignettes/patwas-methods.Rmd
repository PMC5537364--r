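---
title: "Pattern-wide association scanning: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-wide association scanning: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patwas)
```

## The problem and the model

Clinical narratives encode outcome-relevant facts in short, highly
conserved phrases ("*base of tongue*", "*M0,*", "*p16 positive*").
`patwas` treats the discovery of such phrases as a screening problem:
enumerate *every* candidate text pattern that occurs often enough to be
testable, test each against the outcome with a non-parametric statistic,
and rank. The analogy is to a genome-wide association scan, with text
patterns in place of variants and an *occurrence profile* — the binary
vector marking which cases contain the pattern — as the unit object of
testing. Two properties follow from this framing and drive the whole
design:

1. **Exhaustiveness over cleverness.** No prior lexicon or grammar
   decides what is testable; anything conserved enough to recur across
   cases is a candidate. This is what lets the scan surface covariates
   nobody thought to look for, and it is also why multiple-testing
   corrections designed for independent tests do not apply (below).
2. **Interpretability of the output.** Every reported feature is a
   literal text pattern (or a small regular expression over tokens) a
   domain expert can read, grep for, and falsify against the source
   documents.

## Corpus model and text processing

A corpus is an ordered list of cases, each holding documents, each
segmented into sentences of word/punctuation tokens. Case order is
fixed at load time (manifest order of first appearance) and defines the
coordinates of every occurrence profile; this is part of the
reproducibility contract, so the same inputs always produce
byte-identical outputs.

Sentence chunking is a deterministic rule: split after `.`, `!`, `?`
or `:` followed by whitespace, and at blank lines. There is no
abbreviation dictionary, so "*Dr. Smith*" splits — a deliberate trade
of linguistic accuracy for determinism, which matters more here: a
mis-split sentence only shortens the span a pattern may occupy, while a
non-deterministic chunker would break reproducibility. Tokens are
maximal alphanumeric runs (hyphens and underscores internal to words
kept: "*non-keratinising*" is one token), decimal numbers are kept
whole (`2.5`, `1,000`), and every other character is its own token.
Matching is case-sensitive by default because informative clinical
patterns are case-bearing ("*He*", "*SCC*", "*Positive*"); a
`fold_case` option lowers everything for case-insensitive studies.

## Annotation

Token-level annotations add tags to tokens to raise recall: `NUM` (with
the parsed value) on cardinal numbers, `STEM:<stem>` from a
Porter stemmer implemented from the original rule tables (no stemming
package is declared as a dependency; the algorithm is small, rule-based
and frozen, so an in-package implementation keeps behaviour pinned).
Like the reference algorithm, it conflates regular inflections
(*smokes/smoked/smoking* → *smoke*) but not Greek-derived plurals
(*metastasis*/*metastases* stem differently) — a known limitation worth
remembering when reading tagged-search output. Part-of-speech tags and
lemmas are *consumed* from CoNLL-style pre-annotation files rather than
computed: any external tagger can feed the pipeline, and the package
carries no model weights.

Sequence-level annotations raise precision by fusing multi-token spans
into single units: vocabulary concepts ("*head of pancreas*" →
`head_of_pancreas`, tagged `CONCEPT:<id>`) by left-to-right
longest-string matching, applied destructively (the phrase becomes a
unigram, with a `keep_original` escape hatch); and parse-derived group
tokens from Penn-bracketed constituency trees, which are *additive* —
the group coexists with its constituent tokens and the tagged search
may use either. The asymmetry is intentional: concept recognition is
described as a rewrite (the fragment *is* the concept), whereas parse
groups are alternative readings.

Before any combinatorial search, `prune_annotations()` removes every
tag value attached to exactly one distinct surface corpus-wide: such a
tag can only ever reproduce the surface pattern it sits on, so it adds
branching without adding generalisation. On realistic annotated text
this removes the large majority of tags and is what keeps the
`O(c^N)` tagged search tractable.

## Feature search

Surface n-grams are grown one token at a time within sentences; a
candidate is abandoned once its corpus-wide occurrence count falls
below `max(2, min_support)`. Occurrence counts are anti-monotone under
elongation, so this pruning is lossless with respect to the final
support filter, and it is also why `max_len` can default to unbounded:
the data, not a cap, bounds the search. `min_support` defaults to 2 —
a pattern seen in a single case cannot reach significance in any exact
test, and singleton patterns are exactly the ones that explode the
search space. The tagged search defaults to `max_len = 5` because each
position multiplies by the number of alternative representations;
tagged patterns that are purely surfaces are dropped as duplicates of
the n-gram output.

Numeric features take the form *A* 〈NUMBER〉 *B*: for every
`NUM`-tagged token, all flank pairs up to `max_flank_len` (default 3 —
the flanks only need to disambiguate the slot, and longer flanks
duplicate shorter ones with lower support) are candidates, and both
flanks must be non-empty, since a one-sided anchor would match
non-discriminantly. A feature whose flank pair matches more than once
in any single case is discarded outright rather than per-case: an
ambiguous extraction rule is wrong as a rule, not merely missing for
one case. Cases without a match are excluded from that feature's test
(complete-case analysis), with `n_used` reported.

## Association statistics

* Binary × binary: sample odds ratio `ad/bc` with Haldane–Anscombe
  0.5-correction when a cell is zero, reported as natural-log OR, and a
  two-sided Fisher exact p under the sum-of-small-probabilities
  convention (all tables with the observed margins whose probability is
  at most the observed table's, within relative tolerance `1e-7`). When
  the observed table is the modal one the p is exactly 1. This is the
  convention of mainstream statistical software and is cross-checked
  against `stats::fisher.test()` and a from-scratch enumeration oracle
  in the test-suite.
* AUC paths use the rank formulation (ties half-credit) with the
  tie-corrected, continuity-corrected normal approximation to
  Mann–Whitney U (via `stats::wilcox.test`); Spearman's ρ is the
  Pearson correlation of mid-ranks with the t approximation
  (`stats::cor.test`).
* An R×C table is tested by a Monte-Carlo Freeman–Halton estimate:
  tables are sampled from the fixed-margin null with Patefield's
  algorithm (`stats::r2dtable`) and
  `p = (1 + #{prob ≤ observed}) / (B + 1)`.

**No multiple-testing correction is applied by default.** Exhaustively
enumerated patterns are nested and overlapping — every super-pattern's
profile is a sub-vector of its sub-pattern's — so the p-values are
heavily dependent and neither Bonferroni nor Benjamini–Hochberg yields
a meaningful cut-off. The significance threshold `alpha` is therefore
an explicit investigator choice (default 0.0025, the order of magnitude
at which discovered patterns separate from noise in corpora of around a
hundred cases); an optional BH column can be emitted for reference
only. Automated threshold selection is out of scope — an open problem,
not an omission.

Filtering runs before redundancy removal (the filtered set is far
smaller, and the removal decision depends only on profiles, which the
filter does not change). Redundancy removal keeps, within each group of
bit-identical profiles, only the longest patterns ("*extensive liver
metastases*" over "*metastases*"): the statistics are untouched because
p depends only on the profile, and the longer pattern is the more
explanatory rendering of the same evidence.

## Regular-expression induction

N-grams sharing first and last tokens are grouped (length ≥ 2;
each pattern has exactly one boundary key, so groups are disjoint) and
consolidated by star alignment: every member is globally aligned
(Needleman–Wunsch, match +1, mismatch −1, gap −1, traceback preferring
diagonal > up > left — scores and tie order are fixed for determinism
and exposed in the call) against the longest member, and pairwise
alignments are merged column-wise. Columns where all members agree
become literal anchors; each maximal run of disagreeing columns becomes
one element holding the members' gap-stripped subsequences — an
alternation, an optional group when one variant alternates with
emptiness, or an optional alternation. Variants are ordered by
descending member support with ties broken by first appearance among
the members, which keeps the rendering stable under re-runs. Global
(not local) alignment is essential: a wildcard at either end of an
expression would match non-discriminantly, so induced expressions
always begin and end with the shared literal boundary tokens.

Induced expressions are re-matched against the corpus (an expression
may match combinations unseen in any member, so its support can exceed
the union of member supports) and re-scored by the same association
step. All induced expressions are retained and ranked among the n-gram
results even when their p is worse than the best member's — overfitted
aggregates are informative failures and should stay visible — with an
`informative` flag marking expressions whose profile is identical to a
member's.

## Classification

Selected patterns are decorrelated before classification: occurrence
profiles are clustered by UPGMA (average linkage, Euclidean distance;
`stats::hclust`, verified against a naive O(n³) implementation) and cut
at `k = max(2, floor(N/10))` clusters — one covariate per ten cases,
floored, with a minimum of 2 so a classifier always has at least two
covariates to weigh. The minimum-p feature per cluster (ties: larger
support, then pattern order) represents its cluster.

Predictive value is estimated by out-of-bag AUC over bootstrap runs
(default 25). Within each run the *entire* discovery pipeline —
enumeration, testing, filtering, reduction, clustering, representative
selection — is re-run on the bootstrap sample only, and the out-of-bag
cases are scored by re-matching the selected patterns in their
documents. This nested design is the package's choice where the
evaluation split was genuinely open: selecting features once on all
data and then bootstrapping only the classifier is optimistic (the
held-out cases influenced feature selection), and a `nested = FALSE`
switch reproduces that variant for comparison. A run whose out-of-bag
set lacks both classes is redrawn. When nothing passes `alpha` inside a
resample, the full ranked list is used instead, so every run yields
covariates — on null data this simply feeds noise features to the
classifier, which is exactly the behaviour the null calibration checks.
The built-in classifier is Bernoulli naive Bayes with add-one
smoothing and unsmoothed priors; logistic regression is delegated to
`stats::glm` behind the same `fit`/`score` contract, and any external
classifier can be plugged in through it. Boosted decision trees are
out of scope.

## The synthetic-corpus generator

`generate_corpus()` emulates the statistical skeleton of a clinical
corpus, not its language: background tokens are i.i.d. Zipf(1.1) draws
over an artificial vocabulary (Zipf because natural-language token
frequencies are heavy-tailed, so high-frequency background n-grams
arise and stress the ranking exactly as stopword phrases do); planted
phrases are inserted at uniform positions with class-conditional
probabilities; numeric patterns carry Normal values rounded to one
decimal. The reference conditions used across the test-suite are 80
cases, balanced classes, four sentences of 6–12 tokens per case,
vocabulary 60, one binary pattern at insertion probabilities 0.8/0.1
and one numeric pattern with class means 20/10 and sd 3 — sizes at
which the planted effects are strong but the corpus is small enough
that a hundred full pipeline runs fit comfortably in a test session.
Planted tokens are reserved out-of-vocabulary strings by default so
ground-truth counts are exact; `collide = TRUE` mixes them into the
background for realism at the cost of dilution warnings.

What passing these tests shows — and what it does not: recovery of
planted patterns under i.i.d. Zipf noise validates the search,
statistics and ranking machinery end to end, but real clinical text has
burstiness, template boilerplate, negation, misspellings and
inter-document correlation that the generator deliberately does not
model. Results on real corpora must still be read by a domain expert
against the source text; known failure modes include negation
qualifiers absorbed into "positive-looking" patterns and fragments of
boilerplate ranking highly because templates correlate with the
clinic that produced them.

## Numerical and degenerate-input choices

* Fisher p returns exactly 1 for zero-margin and modal tables; `p = 0`
  cannot occur, but volcano output clamps it defensively and flags the
  row.
* Odds ratios with an empty cell are `Inf` unless the Haldane
  correction is on (it is by default).
* `rank_auc` on fully tied data returns p = 1 (no evidence) rather than
  NaN; Spearman on a constant vector returns nothing and the feature is
  skipped.
* All sorting uses radix order (locale-independent); every tie anywhere
  (filtering, representative selection, alternation variants, alignment
  traceback) has a documented deterministic break.
* Empty corpora, empty manifests, label tables referencing unknown
  cases, duplicate labels, and token-count mismatches in
  pre-annotations are fatal with the offending row named; a case
  without labels is retained and simply excluded from labelled
  analyses.

## Problem sizes in the shipped checks

The test-suite validates each search/matching/clustering/testing path
against independent brute-force oracles on hundreds of randomized small
instances (corpora up to ~6 cases × 2 sentences × 20 tokens, tables up
to total 40, alignments up to combined length 12), and the end-to-end
recovery and null-calibration checks run the full pipeline over 100
seeds at the reference conditions above. `scripts/acceptance.R` re-runs
the same quantities at 50 seeds, which reproduces the rates to within
Monte-Carlo error in about two minutes on a single CPU.

## Known limitations

No negation or context detection; no gapped or cross-sentence
patterns; no word-number parsing ("three" is not a cardinal); flat
concept ids without hierarchy traversal; POS/parse annotations must be
supplied externally; redaction is plain substring masking and not a
validated de-identification method; the naive sentence chunker
over-splits abbreviations. Each is a scoping decision documented where
it bites, and the pattern output makes most of them visible on
inspection.
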