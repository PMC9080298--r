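---
title: "Methods: metabolic-profile MoA classification with moaprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic-profile MoA classification with moaprofile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`moaprofile` classifies anticancer compounds into mechanism-of-action (MoA)
classes from the metabolic fingerprint they induce in a panel of tumor cell
lines. This vignette is the package's own account of the statistics: the
model and its assumptions, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the design was
genuinely open.

## The data and their preprocessing

The input is a pair of aligned peak tables — features (retention time, m/z)
by samples — from complementary reversed-phase (RPLC) and
hydrophilic-interaction (HILIC) chromatography, plus sample metadata (cell
line, drug, drug class, treated/control/QC, cell count, injection order).
`align_features()` also provides a simple greedy binning aligner for raw
per-sample peak lists: peaks are pooled, sorted by intensity, and clustered
into a feature whenever they fall within a 0.05 Da mass window and a
0.5 min retention-time tolerance of the feature's seed peak, after
discarding peaks below 5 % of their sample's base-peak intensity. That
intensity floor also stands in for the vendor software's proprietary
noise-elimination setting, which has no public definition.

Preprocessing runs in a fixed, asserted order:

1. **Missing-value filter** — a feature is dropped when its fraction of
   zero intensities is *strictly* greater than `max_missing` (default
   0.20); a feature at exactly 20 % is kept.
2. **Cell-count normalization** — intensities are rescaled to the median
   cell count (`intensity × median(count)/count`); pooled QC samples,
   being mixtures, are left unchanged. Normalization happens *after*
   alignment; the alternative order is defensible but the choice is
   recorded in the provenance.
3. **log10 transform** — remaining zeros are replaced by half the smallest
   positive intensity of that feature (the most common metabolomics
   convention; the zero policy is a parameter). A feature that is zero
   everywhere is an error: the filter should have removed it.
4. **Pareto scaling** — per feature, center and divide by the square root
   of the sample standard deviation (n − 1 denominator). The scaled
   column's variance equals the original column's standard deviation:
   high-variance features are damped, not flattened. Constant features are
   centered and left unscaled. The stored center/scale back-project new
   samples exactly (to 1e-10), which is what lets cross-validation refit
   the scaling per training fold from the scaled container.
5. **Fusion** — feature-wise concatenation of the per-block scaled
   matrices ("RP + HI"), harmonizing sample order by id. Because Pareto
   scaling is a per-feature operation, scaling per block before fusion and
   scaling the fused matrix are numerically identical; no switch between
   them is exposed.

## The classifier

The model is multi-class OPLS-DA built on a NIPALS PLS2 backbone
(`fit_pls2_nipals()`), fitted to the column-centered class indicator
matrix (no scaling of Y; classes are roughly balanced by design).
Orthogonal-variation removal follows the Trygg–Wold construction
generalized to a multi-column Y: one PLS round yields a loading `p`, the
projection of `p` onto the orthonormal basis of X′Y (the Y-predictive
weight space) is subtracted, and the remainder — normalized — defines an
orthogonal component that is deflated from X. After `n_orth` such rounds,
`n_pred = K − 1` predictive components are extracted. Membership
predictions are `Ŷ = X B + Ȳ` with `B = W (P′W)⁻¹ C′`; class assignment is
the argmax of `Ŷ`, with exact ties resolved to the smallest class index
(deterministic, documented, and in practice unreachable with continuous
data).

Model quality is summarized exactly as chemometrics practice expects:

* **R²Y (cum.)** over the predictive components (monotone in their
  number);
* **Q² (cum.)** `= 1 − PRESS/SSY` from stratified sevenfold
  cross-validation in which *both* the Pareto scaling and the model are
  refitted on each training fold. Q² is reported at the final component
  count, not as a per-component product; the simpler definition is
  exposed everywhere as the single `q2` number.
* **VIP**, with `mean(VIP²) = 1` exactly, so VIP > 1 marks above-average
  contributors.

With `n_orth = "auto"`, orthogonal components are added while the
cross-validated Q² improves by more than 0.01, capped at 5. Under the
generator's default conditions one orthogonal component is selected; the
fitted pipelines in this package therefore default to a fixed
`n_orth = 1` wherever a fixed architecture is needed (permutation
replicates reuse the original architecture rather than re-selecting it —
a deliberate choice that keeps the permutation distribution comparable).

### Validation diagnostics

The **permutation test** shuffles the class labels jointly (row
permutation of Y), refits the fixed architecture, and records R²/Q²
together with `r`, the mean absolute column-wise correlation between the
permuted and original indicator matrices. Least-squares lines through all
points, including the unpermuted model at `r = 1`, give the reported
intercepts at `r = 0`; a sound model shows all permuted values below the
originals and a negative Q² intercept. When all permuted `r` sit near
zero — the generic case for a balanced design — the intercept collapses
toward the mean of the permuted metrics, which is the correct degenerate
behavior.

**CV-ANOVA** compares the cross-validated residuals against the total
indicator variation: `SS_reg = SSY − PRESS` on `A` degrees of freedom
versus `PRESS` on `N·K − K − A`, with `p` from the upper F tail (floored
at 1e-300). The degrees-of-freedom bookkeeping of the commercial
implementation is proprietary; ours follows the published CV-ANOVA
formulation as closely as its description allows and should be read as
approximate. `PRESS ≥ SSY` yields `F = 0, p = 1`.

### Marker selection

Per class, features pass the cascade VIP > 1 → one-way ANOVA with
Bonferroni correction → oriented ROC AUC > 0.50. Choices the source
material leaves open, and how they were fixed:

* The ANOVA grouping is **treated vs control within the class**, matching
  the per-class fold-change tables (an all-classes grouping is available
  by calling `anova_bonferroni()` directly with more groups).
* The Bonferroni family is the **per-class VIP-survivor count** — the
  per-class tables define per-class families. `p_adj = min(1, p·m)`.
* Fold changes are ratios of group means on the **cell-count-normalized,
  pre-log intensity scale**, with trend "up" iff FC > 1 strictly; a zero
  control mean makes FC undefined and drops the candidate with a recorded
  reason.
* AUC is the rank-based Mann–Whitney statistic with ties counted 0.5,
  computed **treated vs control** (consistent with the FC contrast) and
  reported both raw and oriented (`max(auc, 1 − auc)`).
* The published marker tables contain repeated metabolite names across
  classes and one compound observed as two ions; `dedup_markers()`
  exposes the deduplication key (`name` or `name + rounded m/z`) instead
  of hard-coding a unique-metabolite count.

The fold-change heat map uses agglomerative clustering with Euclidean
distance and average linkage on the actual FC values, cut into four row
clusters; a constant matrix collapses to one cluster with a warning.

### Classifying new compound sets

New samples are pushed through the stored preprocessing state
(`apply_preprocess()`), the training center/scale, and the model's
orthogonal filter before projection. `classify_set()` reports per-sample
calls, the majority call (an exact vote tie returns `"unresolved"`), the
concordance, a projection fit `R²_pred` under the called class, and a
mixed-mechanism flag raised when the two largest mean memberships differ
by less than `margin_threshold` (default 0.2 — the source decided this
visually; the parameter is exposed). A set whose best mean membership
stays below 0.4 (e.g. untreated controls) is called `"none"` with a
warning rather than silently assigned. With the default frozen-model
projection, the sevenfold re-blocked external Q² necessarily equals
`R²_pred`, because frozen-model predictions do not depend on the
blocking; `refit = TRUE` switches to the alternative reading in which the
model is refitted per block on training plus the remaining new samples.
`region_report()` summarizes where sets land relative to the convex hulls
of the training classes in the first two predictive score dimensions.

## The synthetic-data generator

No raw data accompany the study design this package implements, so
`generate_study()` emulates it: 12 adherent tumor cell lines × 4 drug
classes × 3 drugs per class × treated/control × 3 profiling replicates
(864 biological samples), 300 RP + 200 HILIC features, pooled QC
injections after every 6 samples, and a ground-truth marker manifest.

Generative assumptions, with units and defaults:

* Feature baselines: log10 intensity `~ Uniform(3, 6)`; technical noise
  `noise_sd = 0.1` (log10); cell-line random effect `cell_line_sd = 0.2`
  (log10), shared between a line's treated and control samples. The
  within-class variance across cell lines is not stated anywhere in the
  source material; these values are plausible for a 12-line panel, not
  fitted.
* Planted markers: 12 per class, shifted ±`effect_size = 0.5` log10 units
  (≈ 3.2-fold, inside the 0.004–6.8 fold-change span of the published
  marker tables) in that class's treated samples only. Marker features
  are drawn from the **upper half of baseline abundance**: markers model
  identified, quantifiable metabolites, and a down-shifted marker sitting
  at the detection floor would be censored by the 20 % filter rather than
  measured — recoverability would then be impossible by construction, not
  hard.
* Drugs within a class add a private `Normal(0, effect_size/5)` shift on
  the class markers, so drugs cluster by class without being identical.
* Cell counts: one log-normal count (mean 1e6, CV 0.1) per flask — i.e.
  per (cell line, drug, condition) — applied to that condition's
  replicates, mirroring the one-counted-flask design; intensities are
  multiplied by `count/mean` before missingness.
* Missingness: a detection floor at the 1 % quantile of baseline
  abundance plus Bernoulli dropouts at `missing_rate = 0.05`; both
  mechanisms produce the observed "intensity = 0" signature.
* QC samples: the feature-wise mean of all biological samples (a pooled
  equal-aliquot mixture) with halved technical noise, injected first and
  after every 6 analytical samples.
* One integer seed drives everything; equal seeds give byte-identical
  tables.

What the generator does **not** emulate: chromatographic peak shapes and
raw spectra, retention-time drift, batch effects (the design is
single-batch), correlated metabolite networks (features are independent
given the design effects), dose–response, and any real metabolite
identities. Consequences for interpretation: passing recovery tests shows
the pipeline's statistics behave correctly under the declared covariance
structure, not that the biology of any real compound would be recovered;
and because features are independent, PCA on default synthetic data is
dominated by the cell-line random effect, so class clustering is *not*
visible in the top two principal components (silhouette ≈ 0 or below) —
precisely the situation OPLS-DA's orthogonal filter addresses, and
consistent with a first-two-components variance share far below half.
The PCA unit test therefore checks class clustering in the regime where
class variance dominates (`cell_line_sd = 0.05`).

## Numerical choices

* NIPALS convergence: relative change of the score vector below
  `tol = 1e-10`, iteration cap `max_iter = 2000`. The cap matters: a
  balanced four-class design makes the leading latent directions nearly
  degenerate (the two top eigenvalues of (X′Y)(Y′X) differ by ~1 %), and
  the power iteration legitimately needs several hundred iterations.
  On label-free (null) data the degeneracy is exact in expectation and
  convergence to 1e-10 may be unattainable; `fit_pls2_nipals()` errors by
  default, but the model-level fitters continue with the direction
  reached at the cap — any direction inside the degenerate subspace is an
  equally valid stationary point, and this is what makes null-data
  cross-validation well defined.
* SVD sign ambiguity in PCA is fixed by making each component's
  largest-magnitude loading positive.
* QC drift: a QC sample passes when each of its first two component
  scores lies within `k = 2` standard deviations of that component's
  score distribution over **all** samples (the reference population is a
  parameter; QC-only referencing would be circular).
* Stratified fold assignment deals shuffled within-class indices
  round-robin, so every fold sees every class whenever class sizes allow;
  smaller classes raise an error rather than silently degrading.
* Degenerate inputs have fixed policies throughout: constant features in
  scaling (centered, unscaled), zero within-group variance in ANOVA
  (F = 0/p = 1 for equal means; p floored at 1e-300 for unequal), zero
  control mean in fold change (candidate dropped, reason recorded), a
  class with fewer than three training samples in the hull report
  (error), an exact argmax tie (smallest class index), an exact majority
  tie (`"unresolved"`).

## Problem sizes

The test suite and `scripts/acceptance.R` exercise the generator at its
default scale (864 biological samples, 500 features) for the headline
checks — cross-validated Q², marker recovery against the manifest,
new-set concordance, the mixed-mechanism flag, and the 20-seed zero-effect
null. Permutation testing (99 permutations, sevenfold CV per permutation)
runs on a 6-cell-line, 250-feature design, and the distributional unit
tests on a 3-cell-line, 100-feature design; these sizes are the package's
choice of a thorough-but-brisk default and are parameters, not limits.

## Known limitations

* The orthogonal filter and the Q², CV-ANOVA and permutation conventions
  reproduce the published algorithmic descriptions, not any proprietary
  implementation; numbers from commercial software will differ in detail
  (component auto-selection, df bookkeeping, per-component Q² products).
* `R²_pred`/`Q²_ext` for a projected set answer "how close is this set to
  an ideal member of its called class", which is only one reading of
  per-set fit statistics; the refit reading is available but neither is
  asserted to be the original study's computation.
* Bonferroni within per-class families is conservative; with hundreds of
  VIP survivors a false-discovery-rate procedure would be more powerful.
  The package keeps the published rule.
* The mixed-mechanism margin (0.2 on mean memberships) is a reasoned
  default for a four-class model, not a calibrated decision threshold.
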