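---
title: "Discovering sebum volatilome markers with sparse PLS-DA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sebum volatilome markers with sparse PLS-DA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sebum — the lipid-rich secretion of the skin's sebaceous glands — emits
volatile organic compounds (VOCs) that can be measured by headspace
thermal-desorption GC-MS from a simple gauze swab. Parkinson's disease
(PD) alters this volatilome, and isolated REM sleep behaviour disorder
(iRBD), the strongest known prodromal state for PD, appears to sit part
way along the same molecular trajectory. `sebovol` implements the
statistical side of a discovery study built on that observation: given a
deconvolved feature-intensity matrix (samples × GC-MS features), find the
features that discriminate phenotypes, check which of them show the
prodromal group at an intermediate abundance, which drift monotonically
over repeated visits, and whether any apparent marker is better explained
by a clinical confounder.

The raw instrument side — acquisition, spectral deconvolution, library
annotation — is out of scope; the pipeline starts from the deconvolved
matrix plus sample and feature metadata.

## Preprocessing

Three deterministic stages, in this order:

1. **Annotation filter.** Features annotated as trimethylsilyl (TMS)
   derivatives or siloxanes (column-bleed artefacts), or with a spectral
   library match factor strictly below 70, are removed. Unannotated
   features are kept — they remain legitimate, merely unidentified,
   markers. We filter before normalising, so artefact intensity never
   enters the total-ion count.
2. **Total-ion-count (TIC) normalisation.** Each sample's row is divided
   by its row sum. This absorbs per-sample loading differences (swab
   pressure, sebum amount); multiplying any raw row by a positive
   constant leaves the rest of the pipeline unchanged, a property the
   test suite asserts exactly.
3. **Log transform and autoscaling.** Natural log of `value + offset`,
   where the offset is half the smallest nonzero value of the post-TIC
   matrix — a deterministic, data-derived choice recorded in the run
   manifest, needed because TIC matrices can contain exact zeros. Each
   feature is then centred and scaled to unit sample SD (n−1 denominator
   throughout, as fits small cohorts). During cross-validation the
   autoscaling parameters are learned on the training folds only and
   applied to held-out folds, so no held-out information leaks into the
   model — a guard the tests verify by corrupting held-out rows and
   checking the fitted fold model is bit-identical.

Instrument stability is checked separately: the percentage relative
standard deviation (%RSD = 100·SD/mean) of repeated system-suitability
injections must be strictly below 20 for every compound of the standard
mix.

## The classifier: sparse PLS-DA

With ~75 samples and ~600 collinear features, classical feature-then-fit
workflows overfit. Sparse partial least squares discriminant analysis
(sPLS-DA) performs classification and variable selection in one step:
PLS2 regression of the column-centred one-hot class indicator **Y** on
**X**, with a hard cardinality constraint (`keepX`) on each component's
X-weight vector.

The fit is a NIPALS iteration per component: the Y-score *u* is
initialised from the dominant right singular direction of **XᵀY** (sign
fixed so the largest-magnitude entry is positive — all sign
indeterminacy in the model is resolved this way), then

* *w* ∝ **Xᵀ**u, zero all but the `keepX` largest |*w*| (ties to the
  lower feature index), renormalise to unit norm;
* *t* = **X**w, *c* = **Yᵀ**t/(tᵀt), *u* = **Y**c/(cᵀc);

until the weight update falls below 1e-6 (configurable; cap 500
iterations). Both **X** and **Y** are deflated in regression mode
(**X** ← **X** − t pᵀ with p = **Xᵀ**t/(tᵀt), **Y** ← **Y** − t cᵀ).
With `keepX = p` this is ordinary dense PLS2-DA, and the test suite
verifies per-component score correlations above 0.999 against an
independent reference implementation (mixOmics), as well as exact support
recovery against exhaustive enumeration on small sparse instances.

**Prediction distances.** Predicted dummy scores are
**X**B + ȳ with B = W(PᵀW)⁻¹Cᵀ. Three assignment rules are provided:
argmax of the dummy scores (`"max"`), nearest training-class centroid in
latent-score space (`"centroid"`), and Mahalanobis distance with the
pooled within-class score covariance. `predict()` defaults to `"max"`,
the plain dummy-regression convention. The cross-validation layer,
however, defaults to `"centroid"`, and this is a deliberate,
consequential choice: a class whose mean lies on the segment between two
other class means — exactly the hypothesised geometry of a prodromal
group — has essentially zero covariance with the latent scores, so its
dummy prediction is a flat function that the argmax almost never picks.
On synthetic three-group data with the prodromal group planted exactly
halfway, the argmax rule plateaus near balanced error 0.25 regardless of
sample size, while the centroid rule reaches error ≈ 0. Nearest-centroid
assignment in score space is the standard remedy in the sPLS-DA
literature and is what makes the three-class analysis meaningful here.

**VIP scores.** Feature importance uses variable importance in
projection over components 1..H:
VIP_j = √( p · Σ_h SS_h w²_jh / Σ_h SS_h ), SS_h = ‖c_h‖²(t_hᵀt_h).
Because every w_h has unit norm, Σ_j VIP²_j = p exactly — asserted to
1e-6 relative on every fitted model in the tests. Cumulative views for
each sub-model (components 1..1, 1..2, …) are returned so that different
analyses can designate different component sets.

## Tuning, stability, significance

Model size is chosen by grid search under repeated stratified
cross-validation (default 3 folds × 100 repeats, seeded), with the
**balanced error rate** (mean of per-class error rates) as criterion —
robust to the class imbalance typical of these cohorts. Tuning is
sequential per component: `keepX₁` is chosen by the minimal mean BER of
one-component models, then frozen while `keepX₂` is tuned, and so on;
ties go to the smaller `keepX`. The number of components is the smallest
H whose mean BER is within one SD (of the fold-level BERs at the global
minimum) of the global minimum — a declared parsimony policy, since
"pick from the initial model" is not operational. Exhaustive search over
`keepX` combinations is a documented non-goal.

**Stability.** At the chosen `(ncomp, keepX)` the model is refit on
every training fold of every repeat; a feature's stability is the
fraction of the k × repeats fold fits in which it receives a nonzero
weight on *any* component (per-feature, whole-model counting; the
denominator is fold fits, not repeats).

**Significance.** A feature is significant iff VIP > 1 on the designated
component view *and* stability > 0.8, both strict. The designated views
mirror the three analyses: components {1, 2} for the three-class model,
any component for the longitudinal model, the full model for two-class.
The direction of regulation is the sign of the normalised-scale group
mean difference (disease minus control).

## Screens: intermediacy and longitudinal regulation

Both screens are deliberately descriptive order statements, not tests —
on null data a feature passes the three-way ordering with probability
about 1/3, which the test suite confirms by simulation. They are applied
*after* significance selection, where they refine an already
error-controlled set:

* **iRBD intermediacy**: flag iff the iRBD group mean lies strictly
  between the PD and control means (normalised scale; raw-scale means are
  also reported). Equal PD/control means leave nothing in between, so
  exact ties are unflagged.
* **Longitudinal regulation**: for subjects observed at three visits,
  flag iff the visit-2 mean lies strictly between visits 1 and 3 —
  monotone drift — with direction increasing/decreasing. Means use
  complete-case subjects only; subjects missing a visit are excluded
  with a warning, and fewer than three complete subjects is an error.

Flags depend only on the ordering of means, so they are invariant to any
feature-wise affine rescaling.

## The confounder battery

Markers should reflect disease, not age, sex, BMI, lifestyle or
comorbidity. The battery probes this with heavily constrained random
forests (via `ranger`): tree depth ≤ 3, no split of nodes smaller
than 5, √p attributes drawn per node, class weights inverse to class
frequency, 500 trees (configurable) — constraints chosen for small,
imbalanced cohorts. Data are split 100 times into 66% training / 34%
testing (stratified for classification); per-sample test predictions are
aggregated by majority vote across splits (per-split means are also
reported, since vote aggregation is only one reading of "majority vote
over repeats").

Three probes per confounder:

1. **Adjusted comparison**: refit with the confounder appended as an
   attribute; an aggregated-accuracy improvement of ≥ 10 *percentage
   points* (absolute; a relative mode exists behind a flag) concludes
   confounding. The confounder's impurity-importance rank among all
   attributes, and whether it lands in the top half, is also reported.
2. **Confounder as outcome**: can the significant features predict the
   confounder? Reported as MCC (categorical) or R² on aggregated test
   predictions (continuous), without a pass/fail threshold — the
   original protocol states none.
3. **Correlation screen**: Pearson |r| > 0.5 between any feature and any
   medication/clinical covariate is flagged; zero-variance columns are
   reported as undefined.

MCC uses the multiclass (Gorodkin) generalisation, which reduces to the
familiar binary closed form — verified exhaustively over all 2×2
confusion tables with cell counts ≤ 5 — with the convention that a zero
denominator (e.g. a constant prediction) scores 0, the random level.

Two implementation notes. Attribute columns are sorted by name before
fitting, making results invariant to the column order of the input
matrix (the per-node attribute draw is index-based). And each split's
sampling, fit and prediction run under a pinned RNG state, because the
forest backend consults the global R stream when breaking
prediction-vote ties; without this, repeated runs could differ in the
third decimal of per-split accuracy.

## The synthetic-data generator

`generate_volatilome()` emulates the statistical structure the analysis
assumes, with known ground truth. Log abundance is built additively —

`baseline_j + group effect + visit drift + confounder effect +
subject intercept + sample loading + noise`

— and exponentiated, so effects are multiplicative on the abundance
scale, matching the log transform. Choices and defaults:

* **Cohort**: three groups (PD, control, iRBD) of 25 subjects, 613
  features — the scale of the motivating study design. The longitudinal
  design uses 11 PD subjects × 3 visits, again mirroring the study.
* **Baselines** drawn from N(10, 2²) in natural-log units, spanning
  roughly 3.5 orders of magnitude of abundance — a realistic GC-MS
  dynamic range that makes TIC normalisation non-trivial.
* **Planted effects**: 40 discriminative features shifted ±2 residual
  SDs in PD, with the iRBD group at a fraction α (default 0.5) of the PD
  shift — α strictly between 0 and 1 makes every discriminative feature
  a planted intermediate.
* **Repeated visits** share a subject-level random intercept
  (SD 0.5 log units), so visits are correlated within subject; drifting
  features shift by ±1 SD per visit.
* **Confounders**: age, sex, BMI, comorbidity flags and lifestyle
  variables are simulated per subject. Optionally a set of features is
  driven by age rather than phenotype (`confounder_strength`), and age
  itself can be shifted in PD (`confounder_assoc`), which lets the
  battery be exercised in genuinely confounded and genuinely clean
  regimes. The battery's positive control uses few, weakly
  confounder-driven features with a strongly phenotype-linked confounder
  (so the features alone classify poorly but the added attribute
  classifies well); the negative control uses direct phenotype signal
  and an independent confounder.
* **Sample loading**: a per-sample global log-scale factor (SD 0.5) that
  TIC normalisation must absorb.

The source study publishes no distributional description of its data, so
these defaults are declared stand-ins, all configurable through
`simulation_spec()`. What passing tests show is therefore that the
*pipeline machinery* is correct and well calibrated under a plausible
generative model — planted markers recovered, null data rejected,
confounding flagged when and only when planted. They do not certify
performance on real instrument data, which has structure the generator
deliberately omits: retention-time drift, co-elution, batch effects,
heteroscedastic detector noise, missing values, and annotation error.

## Numerical choices and degenerate inputs

* NIPALS tolerance 1e-6 on the weight update, ≤ 500 iterations; both
  configurable. Initialisation is deterministic (SVD-based), so equal
  inputs give bit-equal models.
* Sparsification ties (equal |w|) break toward the lower feature index;
  argmax/argmin prediction ties break toward the larger training class,
  then label order.
* Zero row sums (TIC), compounds with zero mean (%RSD), classes absent
  from a fold, `keepX > p`, single-class fits, and subjects missing
  visits all raise named errors rather than propagating NaN; constant
  features are dropped with a warning before autoscaling.
* One master seed derives all stage seeds (CV splits, forest splits)
  through a fixed integer map, so a run manifest plus one seed
  reproduces every table byte-for-byte.

## Problem sizes used in validation

The packaged validation runs the full pipeline on 3 × 25 samples × 600
features with 3-fold × 25-repeat cross-validation (the tuning surface is
stable well below 100 repeats on data of this separation, and the
selection thresholds are unchanged), the null control at the same size,
the longitudinal screen on 11 × 3 visits × 300 features, and the
confounder battery at 100 splits of 50 samples × 20 features. On one CPU
the complete suite runs in a few minutes.

## Known limitations

* The screens are order statements without error control; their value is
  descriptive triage after an error-controlled selection step.
* Sequential (greedy) `keepX` tuning can miss jointly optimal
  combinations; exhaustive search is a non-goal.
* The depth-3/√p-attribute forest constraints attenuate single-attribute
  signal: even a confounder copied verbatim into one of eight feature
  columns regresses with R² ≈ 0.5, not ≈ 1. This is the cost of the
  overfitting guard and worth knowing when reading "not predictive"
  results on small attribute sets.
* Kernel, multiblock and multilevel PLS variants, probabilistic class
  outputs, permutation p-values for the model, and causal adjustment
  (propensity methods) are out of scope.
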