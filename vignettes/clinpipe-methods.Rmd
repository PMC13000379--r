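---
title: "Methods: synthetic cohorts, deidentification, multilabel modeling and privacy auditing"
author: "clinpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts, deidentification, multilabel modeling and privacy auditing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clinpipe` implements a complete privacy-conscious clinical data pipeline
— synthetic cohort generation, deidentification, clinical feature
engineering, dual-format persistence, multilabel prediction, formal
equivalence testing, and a membership-inference audit. This vignette
explains the models and procedures behind each stage, the tunable
parameters that matter, and the design choices made where several
defensible options existed.

## The synthetic cohort generator

Real encounter tables cannot be redistributed, so the generator is a
first-class, tested component rather than a fixture: it produces raw
encounter tables with the statistical structure and the data-quality
defects the downstream stages assume.

### Disease-label model

Each patient carries three binary condition labels: hypertension
(`I10.9`), diabetes (`E10`–`E14`) and spinal stenosis (`M48.06`). Labels
are drawn jointly from a log-linear (Ising-style) model over the 8
states of $\{0,1\}^3$:

$$P(y) \propto \exp\Big(\sum_j \alpha_j y_j + \sum_{j<k} \beta_{jk}\, y_j y_k\Big)$$

The pairwise terms $\beta_{jk}$ are the configured comorbidity
log-odds-ratios; the intercepts $\alpha_j$ are calibrated numerically (BFGS
on the log-marginal error over the exactly enumerated 8-state
distribution) so the marginal prevalences equal the configured values to
numerical precision. A log-linear model is the minimal joint distribution
that fixes all three marginals and all three pairwise associations
simultaneously, which is exactly the structure clinically observed
co-occurrence (hypertension–diabetes above independence) requires.

Defaults: spine prevalence 0.50%; hypertension 10% and diabetes 8.5%
(the anchors are package assumptions chosen as plausible adult outpatient
prevalences — they are configuration, not estimates); comorbidity
log-odds 1.5 for hypertension–diabetes and 0.5 for each anchor–spine
pair.

### Visits and codes

Visit counts are Poisson with a mean of 28 encounters per patient,
chosen to match the row-per-patient density of a large single-center
encounter table (tens of millions of diagnosis rows over a few hundred
thousand patients). Visit dates are uniform over the configured calendar
span and sorted within patient; departments follow a home-department
preference (70% stay probability) so multi-department longitudinal
histories and department-boundary episodes both occur.

Diagnosis codes come from three sources: a bundled ~80-code background
pool with Zipf-like base rates, label-specific comorbid/symptom pools
emitted at elevated rates by carriers (these are the predictive signal
that survives defining-code exclusion), and the defining codes
themselves. Every carrier emits at least one defining event and
non-carriers never do, so the patient-level empirical prevalence of a
defining code equals the sampled label prevalence — the generator is
calibrated by construction, up to binomial noise in the label draw.

### Defect injection

`inject_messiness()` adds, at configured fractions: appended duplicate
rows (half exact copies, half with an altered visit type so the
deduplication key still collides), blanked sex fields, verbose sex
strings (`"men"`/`"women"`), and three non-ISO date dialects
(`YYYYMMDD`, `DD/MM/YYYY`, `YYYY.MM.DD`). Injection is seeded and logged
with row indices per defect class, and rows outside the seeded defect
sets are bit-identical to the clean table — which is what makes
"cleaning removed exactly what it should" testable.

### What the generator does not emulate

Prescription and laboratory semantics are filler columns; codes are a
small bundled list rather than a full KCD-8 dictionary; visit timing has
no seasonality or care-pathway structure; and label-code dependence is
stationary across calendar time. Passing tests on these cohorts
demonstrates the pipeline's correctness and its statistical behaviour
under known ground truth — not clinical validity on any real
population.

## Deidentification

Surrogate IDs are uniform random 10-character tokens, regenerated on
collision, bijective against the original IDs, and reproducible for a
fixed seed. Date standardization parses only a whitelisted dialect set
and drops (with counts) anything else — silent coercion of a malformed
date is a data-integrity hazard, so unparseable rows are never guessed.

k-anonymity generalization uses a global band-widening ladder over age
(5 → 10 → 20-year bands by default) with sex as the second
quasi-identifier. The ladder stops at the first rung where every
patient-level (band, sex) class holds ≥ k patients; residual classes at
the widest rung are suppressed (default) or merged into a top band.
Global widening with suppression was chosen over optimal lattice search
because it is simple, auditable, and monotone — the certification step
`verify_k_anonymity()` is a pure read-only minimum over patient-level
class sizes, so the guarantee never depends on the generalizer's own
bookkeeping. Class sizes are counted over distinct patients, not rows;
rows per patient would trivially inflate them.

The quasi-identifier set `[age_band, sex]` is configurable; these are
the only demographics in the modelled schema.

## Clinical transforms

* **Cleansing** normalizes a fixed sex-token map and drops missing or
  unknown tokens with counts. Unknown tokens are never imputed.
* **Deduplication** keeps one row per (patient, date, code). "Most
  recent" is ambiguous when the date is part of the key, so the tie-break
  is last-loaded row — load order is the only ordering left.
* **Episodes** start on a department change or a date gap strictly
  greater than `gap_days`. No canonical gap length exists, so it is a
  mandatory, logged parameter defaulting to 30 days.
* **Rolling features** use a trailing window inclusive of the index
  event, `[d − 89, d]` at the default 90 days, so every event has counts
  ≥ 1 and same-date events share identical window statistics.
* **Monthly aggregates** use calendar months, cohort-level distinct-code
  diversity (a per-patient alternative is configurable), and type-7
  (linear-interpolation) quantiles for the p50/p90 of per-patient
  event counts. Empty months are absent, never zero-filled.

All date arithmetic is in whole days, timezone-free.

## Storage

The CSV dialect is pinned: UTF-8, header row, RFC-4180 quoting, and
nulls encoded as the unquoted sentinel `\N` (the PostgreSQL `COPY`
convention) with empty strings written as quoted `""`. The sentinel
keeps `NA` and `""` distinct under any conforming reader; a data value
equal to the sentinel itself is refused at write time rather than
written ambiguously. Parquet uses the arrow writer's default codec.
Read-side schemas are enforced explicitly — a cast that would introduce
`NA`s fails rather than coercing.

The paired benchmark harness executes io → feature transform → training
under both formats with shared run identifiers and identical seeds.
Timings and memory are hardware-dependent instrumentation: they are
reported for paired statistical comparison, and no acceptance logic in
the package consumes them.

## Feature hashing and leakage control

Patient diagnosis multisets are hashed into $2^{18} = 262{,}144$ signed
sparse features: column index $\mathrm{FNV1a}(code) \bmod 2^{18}$, sign
from bit 16 of a second FNV-1a hash of the code with a fixed suffix.
FNV-1a is re-implemented in pure R (exact in doubles, pinned constants)
so vectors are identical across processes, platforms and library
versions. Bit 0 of FNV-1a is unusable as the sign: the hash's parity is
simply the XOR of its input bytes' parities, which would make the sign a
deterministic function of the index bucket and break collision
cancellation — bit 16 is well mixed.

Before hashing, every code matching any label specification is removed
(`exclude_defining_codes()`); the leakage guard is audited in the test
suite by re-scanning the feature pipeline's actual input surface for
defining codes. Models never see a code that defines a label.

Within the model layer, training and prediction operate on the
active-column submatrix (columns with at least one nonzero training
entry). An all-zero feature can never host a split, so this is
statistically identical to training on the full width while keeping the
tree-builder's histogram scan proportional to the codes actually
observed; `hash_features()` itself always emits the full $2^{18}$
columns.

## Multilabel models

The base learner is a gradient-boosted tree binary classifier with
learning rate 0.08, maximum depth 6, 1000 boosting rounds, the
deterministic CPU `hist` tree method on a single thread, and per-label
`scale_pos_weight` = (#negatives)/(#positives) from the training split.
There is no early stopping; the estimator count is fixed, and the
validation split exists for monitoring only.

One-vs-rest fits the three labels independently. The classifier-chain
ensemble fits 5 chains over distinct label orderings; within a chain the
model for the j-th label consumes the hashed features plus the
*predicted probabilities* of earlier labels. Two open choices were
resolved as follows:

* **Orderings.** With 3 labels there are 6 permutations. The 5 retained
  are those ranked first lexicographically by their prevalence-rank
  vectors — i.e. all orderings except the one that puts the sparsest
  label first and the anchors last in reverse, the ordering that most
  violates the high-prevalence-anchors-first gradient. Overridable via
  the `orderings` argument.
* **Chaining signal at train time.** Earlier-label features are
  out-of-fold predictions from a 2-fold internal refit rather than
  in-sample predictions (optimistic) or true labels (train/inference
  mismatch). At inference the full models' predictions are chained.

Ensemble output is the unweighted mean probability across chains;
decisions threshold at 0.5. Patient-level splits are a seeded shuffle
with largest-remainder allocation at 65/15/20, so counts are within one
patient of exact and no patient straddles splits.

## Metrics and equivalence testing

AUROC uses the midrank statistic (ties count one half); AUPRC is the
step-wise precision-recall integral over descending distinct thresholds.
Single-class truth makes rank metrics undefined and raises an error —
never a silent 0.5. Multilabel metrics follow the standard definitions
(Hamming loss over cells, subset accuracy over rows, row-wise Jaccard
with empty/empty scoring 1, micro over flattened pairs, macro as label
means). Calibration uses the Brier score and an expected calibration
error over 10 equal-width probability bins (configurable; 10 is the
common reliability-diagram default).

Paired-run comparison applies a Shapiro-Wilk gate at 0.05: normal
differences take a paired two-tailed t test, otherwise a Wilcoxon
signed-rank test, with Bonferroni correction across the four headline
metrics (AUROC, AUPRC, accuracy, F1). Equivalence is the Schuirmann TOST
procedure with prespecified margins δ = 0.02 (AUROC/AUPRC) and 0.01
(accuracy/F1); the reported p is the larger one-sided p and equivalence
requires p < 0.05. Runs that converge to identical values produce
zero-variance differences for which both tests are undefined; that
degenerate path is flagged and resolved by direct margin comparison
(|mean| < δ with zero spread), because the scientific question remains
answerable even where the test statistic is not. Bootstrap CIs are
seeded percentile intervals (5000 replicates by default) over the paired
run differences; resampling runs rather than test instances matches the
20-paired-run design, and an instance-level bootstrap can be had by
passing instance-level values.

## Privacy audit

Membership scores are oriented so larger means "more likely member":
confidence $\overline{\max(p, 1-p)}$, negated mean binary entropy, and
negated mean per-label log loss against the true labels (the Yeom
attack). The shadow attack trains pipeline models on disjoint synthetic
cohorts (disjoint id namespaces, with an explicit contamination guard),
fits a logistic attack classifier on (confidence, entropy, loss) score
vectors with known shadow membership, and evaluates it on the target.
LiRA logit-transforms the probability a model assigns to a record's true
labels (clamped to $[10^{-6}, 1-10^{-6}]$), fits per-record Gaussians
over "in" and "out" shadow populations (8 shadow models by default —
the smallest count giving stable per-record fits at desk scale; global-SD
fallback when a side has fewer than 2 observations), and scores by the
log likelihood ratio; an offline out-only z-score variant is included.
Multilabel outputs are reduced by label-averaging, since the attacks are
defined in the literature for single-output models.

Attack metrics: AUC by midrank over member/non-member scores with a
seeded record-level bootstrap CI; advantage = max over thresholds of
(TPR − FPR); best accuracy by exhaustive threshold sweep — an upper
bound, since no separate threshold-calibration set is held out, and
documented as such; gain = best accuracy − max(majority prior, 0.5),
non-negative by construction.

Membership truth is always assigned at patient level. The audit's
expected behaviour is two-sided and both sides are tested: a properly
trained pipeline model on an exchangeable 10,000-patient cohort yields
chance-level AUCs, while a deliberately overfit construction (tiny
cohort, depth 12, high learning rate, no class weighting) must be
detected (loss-attack AUC well above 0.55) — the null result is only
credible if the instrument can detect leakage when it exists.

## Numerical and reproducibility notes

* All stochastic steps take explicit integer seeds and restore the
  caller's RNG state; fixed seeds give bit-identical cohorts, splits,
  bootstrap intervals and (single-threaded `hist`) model predictions.
* Label-model calibration fails loudly if the fitted marginals deviate
  by more than $10^{-6}$ from their targets.
* Probability clamping at $10^{-6}$ precedes every logit or log-loss
  transform.
* Problem sizes used by the test suite and the acceptance script —
  cohorts of a few hundred to 50,000 patients, 20-run equivalence
  designs, 200-replication TOST sweeps, one 10,000-patient audit — are
  desk-scale choices that keep the full suite in the low minutes while
  leaving every statistical check well-powered; all scale knobs are
  configuration.

## Known limitations

The generator's realism caveats above bound what green tests imply about
real EHR data. k-anonymity is certified for the modelled
quasi-identifiers only — it says nothing about re-identification through
diagnosis codes themselves (l-diversity, t-closeness and differential
privacy are out of scope). The best-accuracy attack column is an upper
bound by construction. Calibration post-processing (temperature scaling,
isotonic regression) is deliberately not included.
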