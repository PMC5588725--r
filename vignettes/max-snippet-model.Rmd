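---
title: "Classifying immune repertoires from their highest-scoring snippet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying immune repertoires from their highest-scoring snippet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxsnippet)
```

## The problem

A B-cell receptor repertoire is a bag of thousands of CDR3 sequences of
varying length, and the clinical question — does this patient have the
disease? — is asked of the bag, not of any single sequence. Standard
classifiers want a fixed-length feature vector per patient; summaries such
as diversity indices throw away the sequence content where the signal
lives. `maxsnippet` implements a multiple-instance approach: score every
piece of every sequence, and let the single best piece speak for the
repertoire.

## The model

Every CDR3 is cut into its overlapping k-mers ("snippets", step 1, so a
CDR3 of length L yields L − k + 1 of them; CDR3s shorter than k are
skipped). Each snippet is encoded as a numeric vector; the default
representation maps each residue to its five Atchley factors —
standardized summaries of ~50 physicochemical properties covering
polarity, secondary-structure propensity, molecular volume, codon
diversity, and charge — so a 6-mer becomes 30 features, ordered
position-major. One-hot amino-acid and nucleotide encodings are provided
for comparison.

A single logistic detector scores every snippet:

$$\mathrm{logit} = b_0 + \sum_{i=1}^{N} W_i f_i, \qquad
  \mathrm{score} = \frac{1}{1 + e^{-\mathrm{logit}}},$$

and the repertoire's diagnosis probability is the **maximum** snippet
score. The max encodes the biological assumption that disease-associated
receptors are rare: one genuinely high-scoring snippet suffices for a
positive call, and a repertoire with none stays negative. A probability
strictly above 0.5 is a positive diagnosis (exactly 0.5 maps to negative).

Parameters are chosen by maximum likelihood on labeled patients. The
objective is the usual binomial negative log-likelihood, but evaluated at
the per-patient maximum score; it is computed from the maximum logit via
the log-sigmoid, so saturated scores never produce infinities. The max is
piecewise-differentiable: the gradient flows only through each patient's
argmax snippet (first index on ties), contributing $(p - y)\,x_\text{argmax}$.

## Fitting

The landscape is non-convex (a linear detector under a max is not), so
fitting uses Adam with random restarts: bias starts at 0, weights at
N(0, 1/N~features~) (read as a variance; `init_scale = "sd"` gives the
other reading), 2500 iterations at step size 0.01 with
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$, and the restart
with the lowest final unpenalized training NLL wins. These are the
published settings of the method this package implements; the published
analysis used $10^5$ restarts, and the package default is 1000 with the
count fully configurable — the acceptance-scale analyses in the test suite
use 200 restarts per cross-validation fold.

Every restart's initialization derives deterministically from
`(seed, fold, restart)` through an integer hash, so fits are bit-identical
regardless of execution order, and cross-validation folds are independent
reproducible streams. Patients are sorted by id inside `encode_cohort()`,
making results invariant to input row order.

The inner loop is compiled (RcppArmadillo) and batches all restarts into
one weight matrix. Because every supported encoding is a position-wise
codebook lookup (each position contributes one of at most 20 fixed
vectors), the per-iteration logit computation reduces to tiny
codebook-by-weight products plus code-indexed vector sums over the restart
dimension, which is far cheaper than the equivalent dense matrix product.
Optimizer arithmetic defaults to single precision — the arithmetic of the
mainstream ML frameworks this model family is usually fit with — while
initial/final likelihoods and restart selection are always evaluated in
double precision; `fit_config(precision = "double")` switches the whole
path. Optional L1/L2 penalties, patient-level early stopping, and bagging
over bootstrap resamples of patients are available through `fit_config()`
but default off: the base method is plain maximum likelihood.

## Model selection and inference

`select_model()` compares representations by exhaustive leave-one-out
cross-validation: for each candidate (k, encoding), each patient is held
out once, the detector is refit from fresh restarts on the remainder, and
the held-out prediction is scored. The default grid is the seven
combinations the method was introduced with (k = 4..7 under Atchley
factors, 6 and 18 nt one-hot, 6 aa one-hot). Accuracy ties break toward
fewer features, so the winner does not depend on grid order. The winning
representation is refit on the full cohort (`refit_full()`) to give the
deployable model.

Significance is assessed by label permutation: each permutation shuffles
the patient labels and repeats the *entire* LOOCV procedure, and the
p-value uses the add-one rule
$(1 + \#\{\text{perm} \ge \text{obs}\}) / (1 + n_\text{perm})$ — with 20
permutations all below the observed accuracy this gives $1/21 < 0.05$,
the resolution the original 20-permutation analysis reported. ROC curves
sweep the unique predicted probabilities (ties step simultaneously) and
integrate by trapezoid; the AUC equals the normalized Mann–Whitney U
statistic, which the tests verify.

## Interpretation tools

* `weight_map()` re-indexes the fitted weights as a (position × factor)
  grid — the bijection is tested — for reading which biochemical
  properties at which snippet positions drive a positive call;
  `autoplot()` renders it.
* `top_snippets()` reports each patient's argmax snippet with its source
  CDR3, offset, score (equal to the patient's diagnosis probability by
  construction), and per-residue Atchley values.
* `score_histogram()` bins all snippet scores by diagnosis group and
  counts per-patient snippets above the diagnostic threshold (0.5).
* `encoding_count()` computes how many distinct DNA spellings a peptide
  has under the standard genetic code (product of per-residue codon
  multiplicities, from `Biostrings::GENETIC_CODE`), and
  `degeneracy_comparison()` asks whether diagnostic snippets have fewer
  encodings than non-diagnostic ones. The comparison defaults to a
  two-sided Mann–Whitney test (normal approximation with tie correction,
  via `stats::wilcox.test`) because encoding counts are discrete and
  heavily skewed; the original report of this analysis did not name its
  test, so a Welch t-test is exposed behind `test = "welch"` as an
  alternative, and the default is a documented choice, not a reproduction.
  By default each distinct snippet string counts once per group
  (`unique_snippets = FALSE` weights by occurrence; the original analysis
  did not state which was used).

## The synthetic cohort generator

No patient data are distributed with the method, so the package ships a
generator that emulates the statistical structure the model assumes:
background CDR3s with lengths 6–24 peaking near 14 (typical heavy-chain
CDR3 lengths) and i.i.d. residues, a planted k-mer motif in a configurable
fraction of case patients (1–5 motif-bearing CDR3s per carrier by
default, echoing the handful of above-threshold snippets per case the
motivating study observed), optional cross-patient contamination to
exercise the shared-sequence filter, and optional random-codon nucleotide
backfill for the DNA encoding and degeneracy analyses. Three presets fix
the study conditions used by the test suite:

* `separable` — 12 cases + 12 controls, 100 CDR3s each, an exact 6-mer
  planted twice per case; mirrors the training-cohort scale of the
  motivating study (23 patients).
* `null` — 8 + 8 patients, 30 CDR3s each, prevalence 0. Chance-level
  behavior is scale-free, so the null preset is deliberately smaller;
  it exists to show the pipeline does *not* find signal in noise.
* `biochemical` — as separable, but planting a family of single-position
  Atchley-nearest-neighbor variants of the center motif, for probing
  generalization beyond exact string identity.

What the generator does **not** emulate: V(D)J junctional structure
(gene segments, insertions/deletions), somatic hypermutation lineages,
clonal abundance skew, or the strongly non-uniform residue composition of
real CDR3 loops (a skewed `"cdr3like"` background is available but the
default is uniform). Passing tests on synthetic cohorts therefore
demonstrate that the machinery recovers the signal class it is designed
for; they do not certify accuracy on real repertoires, and the headline
accuracies of the motivating study are not reproducible without its
(undeposited) patient data.

## What the synthetic experiments taught us about the model

Two behaviors of the max-snippet likelihood are worth knowing before
applying it:

* **Capacity vs cohort size.** With few case patients, the lowest-NLL
  solution is often pure memorization: one linear direction can score one
  arbitrary background snippet per case highly, fit training perfectly,
  and generalize at chance. The planted motif only wins the likelihood
  race when the case count and per-patient snippet counts make
  memorization infeasible — around a dozen cases with hundreds of
  snippets each in our experiments, comfortably satisfied by the
  motivating study's 23-patient training set. Unit tests therefore check
  signal recovery at that scale and mechanics at small scale.
* **Specificity needs background mass.** A held-out patient's maximum
  runs over fresh background snippets; if training patients carry few
  snippets, the fitted boundary hugs the training background too tightly
  and held-out controls leak above 0.5. This is inherent to max-pooling,
  not an implementation artifact.
* **Degenerate optima.** Many weight directions achieve near-zero NLL on
  a separable cohort (any shifted window overlapping the plant can carry
  the signal), so recovery is asserted functionally — localization of the
  argmax snippet on the plant — rather than by similarity of the weight
  vector to a canonical direction.
* **Below-chance permutation accuracy is normal.** LOOCV under permuted
  labels tends to score *below* 50% (the fold's training labels
  anti-correlate with the held-out truth); the motivating study's
  permutation mean of 40% shows the same effect.

## Numerical choices and edge cases

* Ties in the per-patient max break to the first snippet index
  (documented, deterministic); automatic differentiation frameworks do
  the same.
* A patient whose repertoire yields no snippets of length k is refused at
  encoding time — the max over an empty set is undefined — never
  defaulted.
* Exactly 0.5 probability maps to a negative diagnosis and is flagged.
* Read filtering keeps reads with length ≥ 300 and mean Phred ≥ 35: the
  removal rules are strict inequalities, so the boundary cases are
  retained.
* Duplicate collapsing keys on the nucleotide sequence when present
  (duplicates are counted before translation), else on the amino-acid
  sequence; collapsing conserves total counts. Duplicate counts are
  carried but do not weight the likelihood — the model is count-agnostic.
* Shared-sequence removal compares amino-acid strings case-insensitively
  and removes a shared CDR3 from *all* patients; a repertoire emptied by
  the filter triggers a warning and is flagged, since no principled
  default exists for it.
* Serialized models embed a checksum of the Atchley table; loading
  refuses a mismatch so a model is never scored under a different
  encoding table.

## Scales used by the shipped analyses

The test suite's end-to-end analyses run the separable preset at 200
restarts × 2500 iterations per LOOCV fold (the published iteration count,
with the restart budget scaled down from $10^5$ as a package choice), and
the null-control permutation analysis at the null preset's smaller scale
(8 + 8 patients, 30 CDR3s, 3 restarts × 500 iterations, 19 permutations,
20 replicates). The oracle checks (likelihood/gradient against brute
force, AUC against the Mann–Whitney statistic, encoding counts against
exhaustive codon enumeration) run at small n where enumeration is exact.

## A worked example

```{r example, eval = FALSE}
library(maxsnippet)

sim <- cohort_preset("separable", seed = 1)
features <- encode_cohort(sim$cohort, k = 6, scheme = "atchley")
cfg <- fit_config(n_restarts = 200, n_iterations = 2500, seed = 1)

fit <- fit_detector(features, cfg)
predict(fit, features)          # per-patient probabilities and argmax snippets
cv <- loocv(features, cfg)      # held-out accuracy
pt <- permutation_test(features, cfg, n_permutations = 20)
top_snippets(fit, features)     # does the model point at the plant?
autoplot(fit)                   # position-by-factor weight map
```

## Limitations

The detector is linear and the aggregator is a hard max; phenotypes whose
signal is distributed across many receptors (so that no single snippet is
decisive) violate the model's core assumption and need softer pooling.
The cross-validation protocol refits the full restart budget in every
fold, which is faithful but expensive; the codebook fast path keeps this
tractable at desk scale. Nucleotide one-hot encodings are implemented as
one-hot indicator blocks; if a categorical integer coding was intended in
the original model-selection grid, accuracies for those two rows are not
comparable.
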