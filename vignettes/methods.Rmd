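---
title: "Models and methods behind metaboCP"
author: "metaboCP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaboCP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metaboCP` implements a complete analysis chain for CSF metabolomics
phenotype classification across two independently acquired LC-MS cohorts:
preprocessing, cross-cohort harmonization, elastic-net signature selection,
transductive Mondrian conformal prediction, and longitudinal monitoring.
This vignette records the models, the assumptions behind them, the tunable
parameters, and the design decisions taken where the methodology left
genuine choices open.

## Data model

A `MetabExperiment` extends `SummarizedExperiment`: rows are quantified
metabolic features (m/z in Da, retention time in seconds, ion mode), columns
are injections. Injections are study samples (with subject, phenotype group
among HC/RRMS/PMS/TRANSITIONING, age, sex, and for re-sampled patients a
timepoint in months), pooled QC injections, solvent blanks, or a two-fold
dilution series of the pooled QC (0.5–32 µL). Intensities are raw or log2;
missing measurements are `NA` and never 0, because true zeros in blanks are
informative. Validity methods enforce unique feature ids, positive m/z,
per-cohort-unique injection orders, and the sample-type-conditional fields
(dilution volume present iff dilution; group present iff study).

## Preprocessing

The per-cohort stages run in a fixed order; each can only shrink the
feature set, and all removals are logged.

* **Blank filter** (`ratio_min = 10`): a feature is kept iff its mean QC
  intensity is at least ten times its mean blank intensity; features absent
  from every blank are kept. The concrete ratio rule is this package's
  formalization of "contaminant removal using blank injections" — the
  threshold is configurable and deliberately conservative.
* **Dilution filter** (`p_max = 0.05`): kept iff the raw intensity has a
  *positive* Pearson correlation with injected volume at two-sided
  p < 0.05. Positivity encodes "originates from the sample"; background
  signals are volume-independent. Constant features are removed (r is
  undefined). For a 6-point series this is equivalent to r exceeding the
  critical value ≈ 0.811 (t with 4 df), which the tests assert.
* **log2 transform**: variance stabilization; zero or negative raw entries
  are a hard error naming the cell.
* **LOESS run-order correction** (`span = 0.2`, degree 1): per feature, a
  LOESS curve of QC log2 intensity against injection order is fitted on the
  QC injections only and evaluated at every injection (direct surface, so
  extrapolation beyond the QC range is linear); the fitted value is
  subtracted and the QC mean added back. Fitting on QCs and applying to all
  injections is the standard QC-anchored reading of drift correction and is
  the testable one: injected drift must vanish from the QCs. When the QC
  count is so small that a span-0.2 window holds fewer than four points,
  the effective span is raised to cover four points — a degree-1 local fit
  is otherwise underdetermined. Features with fewer than five usable QC
  values pass through unnormalized and are flagged rather than silently
  smoothed.
* **QC CV filter** (`cv_max = 0.20`, strict): the coefficient of variation
  is computed on the *de-logged* normalized QC values; CV = 0.20 exactly is
  removed.
* **TIC report**: total ion count per injection; entries beyond 3 MAD from
  the median are flagged, never removed — outlier handling is a human
  decision. When the MAD degenerates to 0, any deviation from the median is
  flagged.

## Harmonization

Features are matched across cohorts within ±2.5 ppm and ±5 s, never across
ion modes. Assignment is greedy one-to-one by ascending combined score
|ppm|/2.5 + |Δrt|/5 with deterministic tie-breaks; optimal bipartite
assignment was considered and rejected as an unneeded dependency for
windows this tight (the synthetic benchmark shows recall ≥ 0.99 with zero
false matches under realistic coordinate jitter).

The intensity-consistency rule — matches must show an "average intensity
deviation less than ±1 standard deviation" — is formalized as
|d_i − mean(d)| < sd(d), with d_i the mean log2 intensity difference of
match i and mean/sd computed once over all candidate matches. Two
degenerate cases are fixed by decision: sd = 0 keeps everything (identical
deviations carry no discriminating information), and fewer than three
matches skips the filter with a warning. Note the rule trims the tails of
whatever distribution d has; it behaves as intended only when most matches
share a common batch shift and a minority misbehave, which is also how the
synthetic generator models cross-batch structure.

Age-associated features are removed by two-sided Pearson p < 0.05 against
age *in the cohort-1 healthy controls only*: patient groups confound age
with phenotype, HC span the full adult range (18–74 in the generator), so
they are the only unconfounded sample. The presence filter (≥ 90%
non-missing, per cohort, boundary inclusive) is computed over study samples
— QC/blank/dilution injections are excluded since downstream modeling never
sees them. Remaining gaps are mean-imputed within cohort and every feature
is then centered within cohort, which makes each imputed cell exactly 0.
The cohort-1 centering means are stored so later samples (follow-up visits)
can be expressed on the same scale.

## Signature selection

Binomial elastic net with mixing α = 0.5 over a 100-point λ grid,
log-spaced from the analytic λ_max down to 0.01·λ_max, on features
standardized to zero mean and unit variance using cohort-1 parameters; the
fit is delegated to glmnet (with its internal standardization disabled).
The objective is glmnet's (1/n)·negative log-likelihood + λ·penalty;
writing the data term as a deviance only rescales λ by 2 and leaves the
path, the CV curve and the selection invariant, so the glmnet convention is
used throughout and the test suite's brute-force optimizer targets that
objective.

Cross-validation uses balanced folds: subjects are shuffled within class
(seeded) and dealt round-robin, so each of the 7 folds receives five PMS
patients and five or six RRMS patients at the study's 35/39 class sizes.
Per λ the held-out binomial deviance is averaged over folds; its standard
error is sd(fold means)/√k; `lambda_1se` is the largest λ whose mean
deviance is within one SE (taken at `lambda_min`) of the minimum. The final
model is refit on all cohort-1 patients at `lambda_1se` (the path fit
itself provides those coefficients); the signature is the non-zero
coefficients ranked by magnitude. AUC on cohort 2 is the tie-corrected
Mann-Whitney statistic, asserted in tests to agree with pair counting and
trapezoidal ROC integration to 1e-12; anti-discriminating features report
AUC < 0.5 as-is.

## Transductive Mondrian conformal prediction

The conformal layer is the package's methodological core and is authored
here in full; only the underlying classifier is delegated (an SVM with
cross-validated sigmoid probability calibration, `e1071::svm(probability =
TRUE)`).

For a test sample x and hypothesized class ŷ, the classifier is retrained
on the training set augmented with (x, ŷ). Every example's margin
nonconformity is computed under its own label, α = 0.5 − (P(y) −
max P(y'))/2, which for two classes is exactly 1 − P(y) (both forms are
implemented and must agree to 1e-12). The Mondrian p-value ranks α_x only
among class-ŷ members of the augmented set, the test sample counting
itself, so p ∈ (0, 1] with numerator ≥ 1. Ties are counted non-strictly
(α_j ≥ α_x), the conservative convention; optional smoothing replaces the
tie count with a single seeded U(0,1) weight, which makes true-label
p-values exactly uniform under exchangeability and is what the validity
tests use. Unsmoothed p-values are the default because they are
deterministic.

One subtlety matters for exactness: the classifier's internal
probability-calibration CV splits by row position, so a test example that
always sits in the last row would occupy a distinguished position and break
the symmetry that the conformal guarantee requires. Each refit therefore
permutes the augmented bag with a seeded draw before fitting; predictions
are made in the original order. Monte-Carlo checks (50 repetitions,
n_train = 80, n_test = 200) confirm per-class error ≤ ε + 2·binomial SE at
ε ∈ {0.05, 0.1, 0.2} and KS uniformity of smoothed true-label p-values.
One statistical detail of that uniformity check: test points evaluated
against the same training set yield *dependent* p-values (conditional on
the training draw their distribution deviates from uniform; only the
mixture over training sets is uniform), so a KS test on the pooled sample
would overstate significance. The check therefore draws one p-value per
repetition and class — independent by construction — and applies the KS
test to those.

Prediction sets at significance ε contain every class with p > ε — empty,
single, or double. The efficiency curve reports the set-size composition
over ε ∈ [0.001, 0.5] (step 0.001, a grid fine enough to resolve the 5–6%
region where single-label predictions peak); the peak-single ε is the
smallest ε attaining the maximum. The calibration curve is the empirical
CDF of true-label p-values, overall and per class. RRMS is always encoded
as class 0 and PMS as class 1.

Hyperparameters follow a two-stage LOOCV accuracy search: stage 1 screens
kernel presets (linear: C ∈ 2^{−3..3}; radial/sigmoid: the same C crossed
with γ ∈ 2^{−7..1}; polynomial: degrees 2–3), stage 2 refines the winning
kernel on a 30 × 30 log-spaced (C, γ) grid (bounds 2^{−5..15} × 2^{−15..3},
configurable); ties break toward smaller C, then smaller γ — the least
complex model among equals.

For longitudinal monitoring, the predictor is trained on all baseline
RRMS/PMS samples of both cohorts *minus every sample of the evaluated
patient* (leave-patient-out), and p-values are computed for the patient's
baseline and follow-up samples; a falling PMS p-value over visits means
decreasing similarity to the PMS phenotype.

## Monitoring statistics

PCA is the SVD of the column-centered (not rescaled — the harmonized
matrix is already within-cohort centered) selected-feature matrix, with
component signs fixed so the largest-magnitude loading is positive;
follow-up samples are projected with the training center. ANOSIM uses
Euclidean distances (configurable; the dissimilarity is a genuine free
choice) through `vegan::anosim`, with permutation p = (hits + 1)/(n_perm +
1) — the convention that never returns 0 — and 999 permutations by
default; the test suite checks the permutation p against full enumeration
at n = 6–8. Note the R statistic's divisor is the standard M/2 with
M = n(n−1)/2 pairs, under which complete separation gives exactly R = 1.
Paired Wilcoxon and Mann-Whitney tests delegate to `stats::wilcox.test`
(exact for small samples without ties; zero differences dropped; the
all-zero case returns p = 1 with a warning). Sex-adjusted log2 fold changes
come from `lm(level ~ group + sex)`; for a two-level factor the group
coefficient equals the marginal-means contrast, which a test verifies
against emmeans. Clinical associations use
`nlme::lme(level ~ clinical + time + sex + time:clinical, random = ~1 |
patient)` by maximum likelihood, reporting the clinical coefficient with
its conditional t-test p-value (residual-df t statistics, no Satterthwaite
machinery) and the strength sign(β)·(−log10 p). Association rows are
clustered with distance 1 − Spearman ρ and average linkage; constant rows,
whose ρ is undefined, are placed last and flagged.

## The synthetic-data generator

`generateCohorts()` emulates the study that motivates the pipeline — it is
the package's test bed, not a fixture. On the log2 scale a study injection
is

μ_f + δ_f·I(PMS) + a_f·age + s_f·I(male) + c_f·I(cohort 2) + g_f(order) + ε,
ε ~ N(0, σ²),

raw intensities are 2^(log2) with uniform missingness. Defaults are the
study conditions: cohort sizes 49/39/35 (HC/RRMS/PMS) and 10/30/16; 500
matched panel features; 10 planted features with |δ| = 0.6 (alternating
sign); 5% age-dependent features with slope 0.025 log2/year (chosen for
essentially full detection power at n = 49 HC given the 18–74 HC age
range; patients' ages follow the per-group means/SDs); 10% of features
carry a ±0.2 sex effect; σ = 0.5; a two-fold 0.5–32 µL dilution series
(the series spans seven injections; the filter accepts any N ≥ 3); QC and
blank injections interleaved every 8 study samples; sinusoidal per-feature
run-order drift with amplitude up to 0.4 log2 units; 5% missingness on
study cells (QC/blank/dilution stay complete so the drift correction and
filters remain well-defined — a simplification relative to real data);
15 contaminants per cohort present in blanks at sample-level intensity and
volume-independent in the dilution series; 40 decoy features placed near a
panel feature in one matching dimension but outside the window in the
other; 30 cohort-only features. The cross-batch shift c_f is a shared
component (0.3) plus tight per-feature scatter (sd 0.15) and an 8%
heavy-tailed outlier minority (sd 1.5), the structure under which the
±1-sd intensity-consistency rule keeps the well-behaved bulk and removes
the outliers; planted and age-dependent features stay in the bulk. Planted
and age-dependent sets are disjoint, since the age filter must be able to
remove the latter without touching the former.

Treated cohort-1 PMS patients (16 by default) are re-sampled at 3/6/12
months with planted-feature means moved a fraction 0.06·month of the way
toward the RRMS mean — about 72% of the gap at one year. Eight clinical
measures are linear combinations of realized planted-feature levels plus a
patient random intercept and noise, two of them null, with all
coefficients recorded in the truth.

A single master seed spawns named sub-streams (features, subjects, noise,
missingness, drift, layout, longitudinal, clinical), so any one component
can be varied without perturbing the others and equal seeds give
bit-identical output.

What the generator does *not* emulate: correlated features (co-eluting
adducts and isotopes), intensity-dependent missingness (an optional mode
exists for mean-imputation stress-testing but is off by default),
heteroscedastic noise, RT warping between batches, and chromatographic
peak-shape artifacts. Passing tests therefore demonstrate correctness of
the algorithms under the stated statistical structure, not performance on
any particular real dataset.

## Problem sizes used by the test suite

The validity checks run 50 repetitions at n_train = 80 / n_test = 200; the
elastic-net recovery check runs 50 seeds at n = 74 × 500 features; matching
fidelity runs 50 generator seeds at full study size; the longitudinal
monitoring check runs 50 seeds with a 120-feature panel (the panel size
only adds nuisance dimensions; group sizes, effect sizes, noise and drift
stay at their defaults). Unit-level property tests use smaller replicate
counts of the same constructions.

## Known limitations

* The transductive design refits the classifier 2·n_test times; at cohort
  scale this is seconds, but it scales linearly in test size and makes no
  attempt at the inductive/split shortcut (explicitly out of scope).
* Conformal validity is exact only under exchangeability; two cohorts with
  systematic differences (the motivating setting!) violate it when
  training on one and testing on the other, which is precisely what the
  calibration curve is for. Joint-cohort leave-patient-out training
  restores exchangeability.
* The 1-SE elastic net does not control signature size tightly: with ten
  strong planted features among 500, the selected set ranges from ~10 to
  ~50 across seeds. The recovery tests document this honestly.
* Mixed-model p-values use conditional t statistics; small-sample
  denominator-df corrections are deliberately not implemented.
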