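---
title: "Methods: case/control plasma LC-MS fingerprinting with plasmafp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case/control plasma LC-MS fingerprinting with plasmafp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmafp)
```

# The problem

Untargeted LC-MS metabolomics of plasma produces a feature table: thousands
of (m/z, retention time) ion signals quantified across samples, with
intensity-dependent missingness and several ion forms per underlying
metabolite. `plasmafp` implements the complete analysis path from such a
table to a per-metabolite "fingerprint" for a small case/control cohort —
the setting of rare inborn errors of metabolism such as mitochondrial
aconitase (ACO2) deficiency, where a handful of patients (here 8, from 4
families) is contrasted against a modest control group (30) and the
diagnostic readout is a panel of TCA-cycle and associated metabolites with
large plasma fold changes.

The pipeline stages, in fixed order:

1. **Pretreatment** — missingness filter, half-minimum imputation, total-sum
   normalization.
2. **Univariate statistics** — signed fold changes, empirical-Bayes
   moderated t-statistics, Benjamini–Hochberg FDR, and the
   `p < 0.05 & |FC| > 1.5` selection rule.
3. **Multivariate models** — NIPALS PCA and OPLS-DA with cross-validated Q2.
4. **Annotation** — exact-mass matching of features to a metabolite library
   through a data-driven adduct/fragment grammar, co-elution grouping, and
   per-metabolite averaging of signed fold changes.

A synthetic-cohort generator with known ground truth makes every stage
testable without patient data.

# Exact-mass arithmetic and the adduct grammar

Neutral formulas are parsed from Hill notation over the element table
C, H, N, O, P, S, Na, K, Cl, Br plus the heavy isotopes 13C, 37Cl, 81Br;
monoisotopic masses use the standard reference values (carbon-12 exact by
definition). An ion form is a declarative rule: atoms added, atoms removed,
optional single-isotope substitutions, and a charge convention. All bundled
forms are singly charged, so m/z equals the ion mass.

Two charge conventions coexist, and the hybrid is deliberate:

* **proton-transfer** forms ([M−H]−, [M+H]+, and the in-source neutral
  losses such as [M−CO2+H]+) shift the mass by one proton, 1.007276 Da;
* **species-attachment** forms ([M+Cl]−, [M+Br]−, [M+CH3COO]−, [M+HCOO]−,
  [M+Na−2H]−) add/remove the neutral monoisotopic mass of the attached
  species with no electron-mass correction.

This hybrid is the unique convention among those we examined that reproduces
the published annotation table's observed-minus-calculated deltas row by
row; 20 of the 32 published rows reproduce exactly at 4 decimals, and the
12 that do not (among them the cis-aconitate [M−H]− row, off by one unit in
the 4th decimal, and the hydroxybutyrate [M−H]− row, inconsistent with
C4H8O3 under any convention) are treated as documented exclusions rather
than fitted.

Two further conventions worth stating:

* **Delta m/z** is observed minus calculated, computed at full precision and
  rounded half-away-from-zero at 4 decimals (base R's `round()` is
  half-to-even and disagrees on ties).
* **Applicability of removals** is checked per element on the organic core
  (C, H, N, O, P, S) only. Salt elements (Na, K, Cl, Br) may be removed by a
  rule without appearing in the neutral formula: the published
  [M−HCOOK+H]+ form of phosphoenolpyruvate loses potassium formate although
  the molecule contains no potassium — the K enters transiently as an
  in-source adduct. A strict all-element check would make that row
  uncomputable.

The grammar is data-driven (`adduct_rules()` reads a tab-separated table
bundled with 18 forms); users add forms by supplying their own file. Form
labels use ASCII brackets (`M-H[-]`).

# Pretreatment

* **Filter**: a feature is eliminated when its missing fraction across *all*
  samples (classes pooled) is ≥ 0.75 — "missing from at least 75% of the
  data", boundary inclusive. Whether the rule should be applied per class is
  genuinely open; the pooled reading is the literal one and is what the
  package does.
* **Imputation**: half the feature's minimum present value, a deterministic
  detection-limit surrogate that is standard in metabolomics. The method is
  a package choice (the upstream description names imputation but not the
  estimator).
* **Normalization**: each intensity becomes a fraction of its sample's
  total, so every sample sums to 1. Normalization runs after imputation
  because it needs complete columns.

The composition filter → impute → normalize is idempotent, and
normalization preserves within-sample ratios exactly. One caveat the tests
make explicit: sum normalization rescales *between*-class ratios by the
ratio of class totals (the closure effect). Fold changes are recovered
exactly only when the class effects cancel in the sample totals; in
realistic tables where background features dominate the total, the bias is
a few percent.

# Univariate statistics

**Signed fold change.** `r = mean(case)/mean(control)` reported as `r` when
`r ≥ 1` and `−1/r` otherwise, so a 36.9-fold reduction prints as −36.9;
equal means map to +1. Near `|FC| = 1` the sign is unstable by construction
(a metabolite whose forms straddle 1 averages toward 0 and is flagged
sign-inconsistent); this degeneracy is inherent to the convention, not a
bug, and only matters for effects far below the selection cutoff.

**Moderated t.** Tests run on log2 intensities (variance stabilization);
fold changes stay on the raw ratio scale. Per-feature pooled variances
`s^2` (residual df `d = n1 + n2 − 2`) are shrunk toward a prior:
`s~^2 = (d0 s0^2 + d s^2)/(d0 + d)`, with the statistic referred to
`t(d0 + d)`. The prior `(s0^2, d0)` is a method-of-moments fit of a scaled
inverse-chi-square distribution via the first two moments of `log s^2`.
With `d0 = 0` the machinery reduces *exactly* to the classical pooled
t-test (verified to 1e-12 against `t.test`); when the spread of the log
variances does not exceed its chi-square sampling value, `d0 = Inf` and
`s0^2` is the geometric mean of the variances, so homogeneous inputs return
their common value unchanged. The finite-`d0` branch agrees with limma's
moment estimator, which the tests use as an independent oracle.

**FDR and selection.** Benjamini–Hochberg step-up q-values (via
`stats::p.adjust`, with an independent brute-force oracle in the tests);
selection uses strict inequalities, `p < 0.05` and `|FC| > 1.5`.

**Family meta-analysis.** Each patient family can be contrasted against the
controls and the per-family p-values combined by Fisher's method
(`X = −2 Σ log p ~ χ²(2k)`); the combiner is a package choice, since the
upstream description cites a meta-analysis without naming one. Zero
p-values are floored at the smallest positive double with a warning.

# Multivariate models

Matrices are unit-variance scaled with centering (the convention of the
SIMCA-class software used for such analyses; `mode = "none"` is available).
PCA uses NIPALS with deflation; the convergence tolerance on the squared
relative score change is set at 1e-20 — far below the 1e-8 accuracy the
tests demand of the dense-decomposition comparison — because power
iteration's successive change understates the remaining error by the
spectral-gap factor. Loading signs follow the largest-magnitude-positive
convention for reproducibility. The default component cap is 16, matching
the depth at which the reference analysis reported its PCA model.

OPLS-DA removes `K` class-orthogonal components (each from the deflated
matrix) and then fits a single predictive component; the predictive score
is orthogonal to every orthogonal score by construction. With `K = 0` the
model is exactly single-component PLS-DA (checked against a direct PLS
computation and mixOmics). `K` may be fixed or chosen by the Q2-improvement
rule (add components while cross-validated Q2 gains ≥ 0.01).

**Cross-validation.** Q2 = 1 − PRESS/SS over 7 folds by default, assigned
venetian-blind after a seeded shuffle and stratified by class for OPLS-DA
(7-fold is the convention of the reference software; the fold count is
configurable, including leave-one-out). For PCA, each held-out element is
predicted from the sample's *other* variables through the training
loadings; the naive row-projection scheme is avoided because it reuses the
element being predicted and cannot go negative on noise. Scaling is
computed once on the full matrix, as the reference software does; the
leakage this implies is noted rather than hidden. Feature ranking is
discriminant-based: absolute covariance between the scaled data and the
predictive score, ties broken by feature id.

# Annotation

Every (metabolite, form) theoretical m/z of matching polarity is compared
to every feature; matches within an absolute tolerance (default 0.003 Da)
are kept. An absolute window rather than ppm is the default because the
panel lives below m/z 250 and the largest published |delta| is 0.0014 Da;
a ppm criterion at these masses would be tighter than the instrument
accuracy the deltas imply. When a metabolite matches several features they
must co-elute: the largest subset spanning ≤ `rt_window` seconds (default
10 s) is retained. This constraint is what separates genuinely
mass-coincident panel members — isocitrate [M+Cl]− and phosphoenolpyruvate
[M+CH3COO]− differ by 0.2 mDa — and it mirrors how multiple ions are
correlated to one metabolite in practice. Features matching more than one
metabolite (isobars such as citrate/isocitrate, identical formula C6H8O7)
are reported with an ambiguity flag on all claimants rather than resolved;
MS/MS fragmentation, the method that resolves them experimentally, is out
of scope.

The per-metabolite fold change is the plain arithmetic mean of the signed
per-feature fold changes of its matched forms — no intensity weighting —
reported to 1 decimal in the fingerprint report.

# The synthetic cohort

`cohort_design()` defaults encode the study conditions: 8 cases in families
of 2, 3, 2, 1 versus 30 controls; the nine-metabolite panel planted at the
reported average fold changes (cis-aconitate −36.9, isocitrate −17.7,
alpha-ketoglutarate −4.3, succinate 1.1, fumarate −1.4, malate −1.1,
phosphoenolpyruvate −6.9, glutamate 1.8, hydroxybutyrate −21.8); Gaussian
mass error with sd 0.0005 Da; log-normal intensity noise with CV 0.2;
baseline missingness 0.1; 1000 background noise features uniform over the
67–1000 m/z acquisition range and a 60–840 s retention window.

Choices where no upstream value exists, fixed once:

* **Base abundances** per metabolite (1.5e5–5e6 ion counts) and a uniform
  0.05–1 relative abundance per ion form — plausible plasma magnitudes; the
  upstream work reports no per-sample intensity distributions, so these are
  chosen for plausibility, not fidelity.
* **Missingness model**: logistic in log intensity with scale 0.5 log
  units, threshold solved so the expected overall rate equals
  `missing_rate`, inflation capped at twice the baseline. The cap keeps
  even 30-fold-suppressed case signals partially observed, which is what
  makes detection-limit censoring stress the filter/imputation path without
  erasing the effect entirely. The class effect is applied *before*
  missingness for the same reason.
* **Randomness**: a single seeded stream with a fixed, documented draw
  order (samples, then panel features, then noise features, then intensity
  noise, then missingness), so a design plus seed is fully reproducible.

What the generator does *not* emulate: chromatographic peak shapes,
retention-time drift, batch effects, correlated metabolite panels, isotope
envelopes beyond the explicitly requested heavy-isotope forms. Passing
tests on this generator therefore demonstrate the pipeline's statistical
and chemical bookkeeping, not robustness to instrument drift.

# Problem sizes and what the checks show

The packaged checks run the full pipeline on the default 1032-feature,
38-sample cohort (a deliberate desk-scale size; the stages are linear in
features and the whole run takes seconds). On that cohort, planted
metabolites with |FC| ≥ 4 are recovered within ±20% (typically within
10%), all planted features whose planted effect exceeds the 1.5 cutoff are
selected at the package-default seed, under 1% of noise features pass
selection, noise p-values are uniform within exact binomial bounds, and
OPLS-DA reaches R2Y and 7-fold Q2 above 0.9 while label permutation drives
Q2 to zero or below. The published study-scale numbers (758 selected
features; PCA R2X 0.66 / Q2 0.43; OPLS-DA R2X 0.41 / R2Y 0.94 / Q2 0.88;
overall FDR 0.01) depend on the unavailable patient LC-MS matrix and are
represented only through these property-level surrogates; the published
per-metabolite fold changes live on as the generator's planted defaults.

# Known limitations

* Sum normalization's closure bias shifts every fold change by the class
  total ratio; with a strongly asymmetric panel and few background
  features, recovered effects are systematically off by that factor.
* The signed fold-change convention is degenerate near |FC| = 1 (the
  succinate/malate regime): averaged values can straddle zero and are
  flagged, not fixed.
* Exact-mass annotation cannot separate isobars; ambiguity flags are the
  honest output.
* Q2 is computed on a globally scaled matrix (reference-software
  convention), which slightly flatters small-sample models.
* The moderated-t prior assumes a common variance model across features on
  the log scale; features imputed heavily at half-minimum violate it
  mildly.

# A worked example

```{r, eval = FALSE}
library(plasmafp)

design <- cohort_design(seed = 1)
cohort <- generate_cohort(design)
result <- run_pipeline(cohort$table, run_config(seed = 1), dir = "out")

result$annotation$summary
result$oplsda$metrics
head(fingerprint_report(result$annotation))
```
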