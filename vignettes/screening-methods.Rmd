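---
title: "Classifying citations for systematic reviews: models, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying citations for systematic reviews: models, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenburden)
```

## The screening problem

A systematic review begins with a search that returns thousands of
bibliographic citations, of which typically only a few percent are
provisionally eligible. Best practice is dual screening — two reviewers
independently judge every title and abstract — which doubles an already
heavy workload. `screenburden` models a division-of-labor alternative:
each reviewer screens half the citations once, a classifier trained on
one reviewer's judgments is applied to the other half, and disagreements
between the classifier and the human are flagged for reconsideration.
The quantity of interest is the *reduction in screening burden* (RSB):
the first pass is halved by construction, and the second pass shrinks by
`100 − mean classification error` percent.

## Corpus model

A corpus is a tibble of citations — id, title, abstract, journal,
indexing terms, and an `include`/`exclude`/`unknown` label — read from
MEDLINE nbib, RIS, or a JSONL dialect. Citation ids prefer the record's
own key (PMID, accession, DOI) and fall back to a stable hash of title
and journal, since bibliographic exports do not share an id scheme.
Composed documents write the **title twice**, ahead of the abstract,
journal, and indexing terms: titles are short and dense, and
overweighting them consistently improves screening classifiers. Fields
remain individually addressable (one field per line), so title bigrams
come from the single title and concept matching can operate per line.
Missing abstracts — 4–24% of records in real screening corpora — are
kept empty, not imputed.

## Five feature sets

* **Alphabetic** — lowercase, split on every non-alphabetic character,
  drop stop words (a fixed Snowball-style list shipped with the
  package), keep tokens of 3–100 characters, then Porter-stem; plus
  underscore-joined bigrams from titles. Features in fewer than 3
  citations are pruned. The stop-word and length filters run before
  stemming; the order is documented because it is not externally
  fixed.
* **Alphanumeric+** — unstemmed alphabetic tokens, plus tokens with
  internal digits or punctuation (`h3n2`, `a/sydney/05/97`,
  `case-control`, `2004-2005`; em/en dashes normalized to hyphens),
  title bigrams, and one journal-name feature per citation. No
  pruning. Tokens shared between the two tokenizers are deduplicated,
  with the alphabetic pass contributing them once.
* **Indexing** — controlled-vocabulary descriptors (MeSH/Emtree
  style). `Descriptor/qualifier` terms contribute both parts as
  features; the major-topic `*` marker is preserved as printed, so
  starred and unstarred uses are distinct columns.
* **Review concepts** — a user-supplied lexicon of surface terms mapped
  to concepts, matched case-insensitively per line with a longest-match,
  non-overlapping rule. Weights are concept counts (no idf), because
  concept vocabularies are small and curated.
* **Topics** — LDA topic probabilities plus two divergence features
  (below).

Lexical sets are weighted by `tf × log10(N/df)`. The base-10 logarithm
follows the textbook convention; the base only rescales every weight
and does not affect the classifier's decisions. Feature columns are
ordered by sorted vocabulary so identical corpora always produce
identical matrices.

Feature selection keeps columns whose information gain for the label is
at least 0.001 bits. Presence/absence binarization (weight > 0) is used
because the threshold is on the bits scale and no finer discretization
is externally specified. Inside the evaluation protocol the filter is
computed on training documents only, to keep test halves untouched.

## Complement naive Bayes

With a few percent of citations eligible, a conventional naive Bayes
starves the minority class. The complement variant estimates each
class's parameters from the *other* classes' documents:

```
w(c, i) = log[ (N(¬c, i) + α) / (N(¬c) + αV) ]
score(c) = − Σ_i f_i · w(c, i),   predict argmax score
```

Real-valued tf-idf weights enter the complement sums directly, matching
the weighting the pipeline declares. The optional weight normalization
divides each class's weight vector by the sum of its absolute values;
this is the "weight-normalized" reading of the classifier's
normalization switch, chosen over document-length normalization because
it is the variant defined alongside the complement estimator (length
normalization can be applied upstream to the matrix if wanted).
Argmax ties go to `exclude`, the majority class, which minimizes false
positives on zero-information documents; all-zero vectors fall back to
the larger class prior and are flagged low-confidence.

A practical note the test suite encodes: the dangerous end of the
smoothing grid for imbalanced data is *small* α. Features never seen in
the handful of include documents acquire complement weights near
`log(α/N)`, and at α = 0.001 with a large vocabulary every prediction
collapses to `exclude`. Large α degrades gracefully toward a centroid
rule because the argmax is invariant to the overall scale of the weight
differences. The grid search exists precisely to navigate this.

## Topic features

LDA is fit per review on alphanumeric+ tokens by collapsed Gibbs
sampling, with `alpha = 50/T` and `beta = 0.1`. The sampler is written
in C++ with its own integer-seeded generator so fits are bit-identical
across runs and platforms. The number of topics is chosen by the
harmonic-mean approximation to the marginal likelihood: post-burn-in
samples of the assignments give `log P(w|T) ≈ log S − logsumexp(−log
P(w|z_s,T))`, and the best `T` maximizes the estimate. Burn-in defaults
to 200 sweeps with samples every 10 — values chosen as conventional
MCMC practice, configurable, not externally prescribed.

Each document then contributes `T` topic probabilities plus two
divergence features: the symmetric Kullback–Leibler divergence (mean of
the two directions, base-2 logs) to the *include medoid* and to the
*exclude medoid*, where a class medoid is the per-topic median of the
class's document-topic distributions, epsilon-smoothed (1e-10) and
renormalized since medians need not sum to one. The mean-of-directions
reading of "symmetric KL" is implemented rather than Jensen–Shannon;
both are premetrics, and the choice is flagged here because the term is
ambiguous. Medoids are computed on training documents only; held-out
documents are folded in by Gibbs sampling with the trained topic-word
counts held fixed, preserving test independence.

### A limitation worth knowing

On desk-scale corpora (hundreds of documents, ~100 tokens each) the
harmonic-mean criterion does **not** recover a small true topic count:
its score increases from T = 5 to T = 20 on every synthetic condition we
generated, because with `beta = 0.1` splitting a topic's vocabulary is
rewarded until tokens-per-topic falls below `V·beta`, which a
20,000-token corpus never reaches. This is a known upward bias of
harmonic-mean marginal-likelihood estimates, and it is consistent with
the method preferring topic counts in the hundreds-to-thousands on real
review corpora. The estimator itself is verified against exact
enumeration on tiny corpora; treat selected `T` values as a useful
operating point, not as an estimate of a "true" topic number.

## Study-design engine

`stratified_half_split()` randomizes citations into halves A and B,
per-class, so the eligible percentage matches to within one citation.
`grid_optimize()` searches normalization × smoothing
(`{true,false} × {.001,.25,.5,.75,1}` by default) with 5 repetitions of
stratified 2-fold cross-validation per cell — 100 train/validate
iterations for the default grid — scoring each cell by the unweighted
mean F3 across its 10 validation folds. F3, the harmonic mean weighting
recall nine times precision, matches reviewer behavior: missing an
eligible study is far costlier than reading an extra abstract. Features
are rebuilt on each CV-training fold and validation folds are projected
into that space, so no validation label ever influences the filter or
the idf weights.

`ab_protocol()` then runs the two independent tests — train on B, test
on A, and vice versa, each direction doing its own grid optimization —
and reports per-test and averaged recall, precision, F3, classification
error, and second-pass RSB. The baseline every run is compared against
is the all-include classifier: recall 1, precision equal to the test
half's eligible fraction, F3 = `baseline_f3(rate)`. Using the test
half's own rate (rather than the pooled rate) is configurable behavior;
the difference is a rounding-level detail at realistic corpus sizes.
First-pass RSB is a constant 50% by design (single rather than dual
review) and is reported as such, never recomputed.

Cross-review comparison uses Friedman's two-way analysis of ranks with
blocks = reviews and treatments = feature sets, with average ranks on
ties and the standard tie correction
`C = 1 − Σ(t³−t) / (n(k³−k))`. The implementation is cross-checked in
the tests against `stats::friedman.test` on random tied data and
against published five-review rank statistics.

## Synthetic corpora

`generate_screening_corpus()` emulates the shape of real screening
datasets: a Zipf-distributed background vocabulary of pronounceable
pseudo-words (so both tokenizers see them), titles of 5–15 and
abstracts of 50–250 tokens, an eligible rate defaulting to 5.8% (the
median of real review corpora), planted discriminative terms whose
sampling odds are multiplied by `effect` in include documents,
class-dependent indexing-term rates, and 10% missing abstracts (inside
the observed 4–24% range). The include count is exactly
`round(rate × n)`. What it does **not** emulate: topical coherence,
realistic MeSH hierarchies, correlated terms, near-duplicate records,
or concept drift across review updates — so green tests here
demonstrate the machinery is correct under its stated model, not that
any particular performance level transfers to real reviews.

Test problem sizes are deliberately desk-scale — corpora of 100–2000
citations, vocabularies of a few hundred to a few thousand, small
candidate-T grids — which exercises every code path while keeping the
default suite fast.

## Numerical choices

* tf-idf: raw tf, `log10`, df from the training half at projection
  time; a term in every document gets weight exactly 0.
* Information gain: base-2 entropies; tiny negative rounding clipped to
  0; single-class corpora are an error because selection is vacuous.
* Medoid smoothing 1e-10; KL inputs are smoothed and renormalized
  before dividing.
* Gibbs sampling: integer-seeded 64-bit generator yielding 53-bit
  uniforms; assignments are exactly reproducible for a given seed.
* Derived seeds for folds, splits and directions come from a fixed
  integer mix of the user seed, kept below 2³¹.
* Friedman χ² with all-tied rows: the tie correction denominator hits
  zero exactly when the numerator does; χ² is reported as 0.

## Interfaces

Every user-facing function takes the corpus tibble first and returns
tibbles, so experiments chain with the pipe; fitted objects provide
`tidy()`/`glance()` and results provide `autoplot()`. A thin command
line (`inst/cli/screenburden`) exposes convert/label/features/topics/
train/evaluate/run/compare/simulate over the same functions for
shell-driven use.
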