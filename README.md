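# clinpipe

`clinpipe` is an R toolkit for building and auditing privacy-conscious
clinical data pipelines on electronic health record (EHR) encounter tables,
aimed at medical-informatics researchers and clinical data engineers who
need to show that a storage or preprocessing change preserves both
predictive performance and patient privacy. Because real encounter data
cannot be shared, the package ships a calibrated synthetic EHR generator so
that every stage — deidentification, feature engineering, modeling,
equivalence testing and membership-inference auditing — is exercisable and
testable end to end without any protected data.

## What it implements

**Synthetic EHR generation.** Patient-level disease labels for three
conditions — essential hypertension (ICD-10 `I10.9`), diabetes mellitus
(`E10`–`E14`) and lumbar spinal stenosis (`M48.06`, 0.50% prevalence) — are
drawn from a log-linear (Ising-style) model
P(y) ∝ exp(Σⱼ αⱼ yⱼ + Σⱼ<ₖ βⱼₖ yⱼ yₖ), with intercepts αⱼ calibrated so the
marginals match the configured prevalences exactly under the pairwise
comorbidity terms βⱼₖ. Carriers emit defining and comorbid diagnosis codes
over Poisson visit histories; configurable fractions of messy dates,
missing/verbose sex codes and duplicate rows emulate raw-feed defects.

**Deidentification.** Random surrogate IDs (bijective, seed-reproducible),
ISO-8601 date standardization over a whitelisted dialect set, and
generalization of quasi-identifiers (age band × sex) along a widening
band ladder until every patient-level equivalence class holds at least
*k* = 5 patients, with suppression of residual classes and a read-only
`verify_k_anonymity()` certification.

**Clinical transforms.** Sex cleansing (`"men"` → `M`, `"women"` → `F`),
keep-last deduplication on (patient, date, code), episode segmentation by
department change or >30-day gaps, trailing 90-day rolling diagnosis
count/diversity per event, monthly aggregates with p50/p90 patient-month
quantiles, and target-condition extraction by exact code or prefix range.

**Dual-format storage.** CSV (RFC-4180, pinned dialect) and Parquet writers
and readers with cell-exact round-trip guarantees, a compression-ratio
probe, and a paired-run timing harness that shares run identifiers across
formats (timings are instrumentation, never assertions).

**Multilabel modeling.** Per-patient diagnosis multisets — with all
label-defining codes strictly excluded — are hashed into 2^18 = 262,144
signed sparse features (FNV-1a index hash, second-hash sign bit). Patients
split 65/15/20 at patient level (seed 42). Gradient-boosted trees
(learning rate 0.08, depth 6, 1000 estimators, `scale_pos_weight` =
N₋/N₊) are fitted one-vs-rest or as an ensemble of 5 classifier chains
ordered along the prevalence gradient, with out-of-fold chained
predictions and mean-probability aggregation.

**Evaluation and equivalence.** AUROC (midrank), AUPRC (step-wise),
accuracy, F1, Hamming loss, subset accuracy, Jaccard, micro/macro
averages, Brier score and 10-bin ECE; Shapiro-Wilk-gated paired t /
Wilcoxon tests with Bonferroni correction; TOST equivalence (margins
δ = 0.02 for AUROC/AUPRC, 0.01 for accuracy/F1) and 5000-rep percentile
bootstrap CIs over 20 paired runs.

**Privacy audit.** Membership-inference attacks — confidence, entropy,
loss (Yeom), shadow-model, and LiRA (per-record Gaussian likelihood
ratios on logit confidence) — against pipeline-trained models under
patient-level membership splits, reporting attack AUC with bootstrap CI,
advantage (max TPR − FPR), best accuracy and gain over the majority
baseline.

## Worked example

```r
library(clinpipe)

raw <- generate_cohort(generator_config(n_patients = 10000, seed = 42))
std <- standardize_dates(raw)
cln <- cleanse(std$table)
ded <- deduplicate(cln$table)

sur <- assign_surrogates(ded, seed = 42)
gq  <- generalize_quasi_identifiers(sur$table, anonymity_policy())
verify_k_anonymity(gq$table)
#> [1] 22

sapply(c(hypertension = "I10.9", diabetes = "E10-E14", spine = "M48.06"),
       function(s) empirical_prevalence(ded, s))
#> hypertension     diabetes        spine
#>       0.0951       0.0871       0.0053

X  <- hash_features(patient_code_multisets(ded))   # 10000 x 262144
Y  <- build_label_matrix(ded)[rownames(X), ]
sp <- split_patients(rownames(X), seed = 42)
cc <- fit_cc_ensemble(X[sp == "train", ], Y[sp == "train", ])
P  <- predict_proba(cc, X[sp == "test", ])
binary_metrics(Y[sp == "test", "spine"], P[, "spine"])
#> spine  AUROC 0.999  AUPRC 0.936  acc 0.999  F1 0.909
```

The prevalences land at their configured marginals (the sparse spine
label at ≈0.5%), the k-anonymity floor of 22 certifies the k = 5 policy
with margin on this cohort, and held-out discrimination is near-ceiling
because the generator plants genuine comorbid-code signal that survives
defining-code exclusion.

A privacy audit of the same pipeline is one call:

```r
audit <- full_audit(pipeline_config(generator = generator_config(n_patients = 10000)),
                    strategies = c("confidence", "entropy", "loss"), seed = 42)
audit$auc
#> [1] 0.509 0.509 0.510      # chance level: no measurable membership leakage
```

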