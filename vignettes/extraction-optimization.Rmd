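---
title: "Response-surface optimization and downstream analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface optimization and downstream analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desirsm)
```

This vignette is the package's account of the statistics it implements, the
choices that were genuinely open, and what its tests do and do not
establish.

## The design and its coding

A central composite design for k factors consists of a full two-level
factorial at coded ±1, two axial points per factor, and replicated centre
points, for 2^k + 2k + n_center runs. Each factor is described in natural
units by a centre, a step (natural units per coded unit — half the
factorial range) and its two axial levels, and coding is always computed as
(natural − centre)/step.

A deliberate departure from textbook presentations: axial positions are
specified **per factor in natural units**, not through a single axial
distance α. Real experiments round axial levels to practical values; in the
packaged dataset the ethanol and temperature stars code to ±2 while the
time stars (15 and 150 min around a centre of 82.5 with step 37.5) code to
±1.8. A single rotatable α = 1.682 could not reproduce those levels. Coded
values are consequently never assumed — they are always derived from the
natural levels, and `code_points()`/`decode_points()` are exact inverses.

Canonical run order is standard order (factorial block, then axial pairs
per factor, then centres). Run tables measured in randomized order are
accepted by `match_runs()`, which matches rows by factor settings, never by
position.

## The quadratic model and its ANOVA

`fit_quadratic()` fits the full second-order polynomial (intercept, k
linear, k(k−1)/2 interaction, k quadratic terms) by QR-based OLS on the
coded predictors. Fitting in coded units is the default because it
reproduces the coefficient scale conventionally reported for CCDs;
natural-unit fitting is available (`coding = "natural"`) but the two are
exact reparameterizations of the same surface.

`rsm_anova()` reports:

* **Per-term partial SS** — the extra sum of squares of each single-df term
  given all others, computed as b²/[(X'X)⁻¹]ⱼⱼ. For a CCD the linear
  columns are orthogonal to each other and to the intercept, so partial and
  sequential SS coincide for them (tested); the quadratic columns are not
  orthogonal to the intercept, so partial SS is the meaningful choice
  throughout.
* **Pure error** — Σ over replicate groups of within-group squared
  deviations; replicate groups are runs with identical factor settings (the
  centre replicates in a standard CCD). Lack-of-fit SS is the residual
  remainder, and F_LOF = MS_LOF/MS_PE. With no replicated runs both rows
  are dropped with a warning rather than silently reporting a residual as
  pure error.
* **Fit statistics** — R², adjusted R², CV% = 100·√MSE/ȳ, and adequate
  precision, computed as (max ŷ − min ŷ over the design points)/√(p·MSE/n).
  The adequate-precision form follows the convention popularized by DOE
  software; because vendors do not document it identically, it should be
  read as a signal-to-noise indicator (> 4 adequate) rather than a
  portable statistic.

p-values come from the F distribution, and significance labels use 0.05.
`reduce_model()` performs backward elimination of non-significant terms,
removing the largest p first (ties broken by canonical term order) and
**preserving hierarchy**: a linear term is retained while any higher-order
term containing its factor remains. This mirrors the common practice of
"removing non-significant terms to improve the fit" while keeping the model
well-formed under affine recoding.

## Desirability optimization and validation

Each response is mapped to d ∈ [0,1] by a Derringer ramp: for a maximize
goal, d = 0 at or below L, ((y−L)/(T−L))^s between the bounds, 1 at or
above T; minimize is the mirror; a target goal ramps up to the target and
back down. The composite D is the weighted geometric mean, which is 0
whenever any individual d is 0 — a response at its worst level cannot be
traded away.

Open choices, decided as follows:

* **Default bounds**: L and T equal to each response's observed minimum and
  maximum in the run table (`observed_range_goals()`). This is the usual
  software default when the analyst states no explicit limits, and it makes
  the optimum's D interpretable as "fraction of the observed range
  achieved".
* **Default weights and exponents**: all 1. There is rarely a principled
  reason to do otherwise without a cost model.
* **Search region**: the full coded design region bounded per factor by the
  axial levels. Optima of well-behaved second-order fits on CCD data are
  interior; bounding at the axial levels avoids extrapolating the quadratic
  beyond where it was estimated.
* **Optimizer**: exhaustive evaluation on a 41-points-per-axis grid, then a
  Nelder-Mead polish started from the best cell, with proposals clamped to
  the region. Both stages are deterministic, and the polished value can
  never drop below the grid value (enforced, and tested). 41³ ≈ 69k
  evaluations is instantaneous for vectorized polynomial evaluation and
  fine enough that the polish starts inside the right basin.

Validation follows the RSD convention for a predicted/experimental pair:
std is the sample standard deviation of the two values
(|e − p|/√2) and RSD% = 100·std/mean, with RSD% < 10 as the pass rule.

## Assay arithmetic

Calibration curves are straight lines absorbance = slope·conc + intercept;
conversion to equivalents inverts them exactly. Percent inhibition is
100·(1 − A_sample/A_control); negative values (pro-oxidant behaviour) are
reported, never clipped. IC50 estimation defaults to a four-parameter
logistic fitted by Levenberg-Marquardt with deterministic data-derived
starting values (asymptotes from the response range, IC50 from the dose
nearest the half-maximum, hill = 1); the log-linear interpolation method is
available and serves as the documented fallback when the 4PL does not
converge. Interpolation works on log10(dose), standard practice for
dose-response data, and fails explicitly when 50% is never crossed.

## Chemometrics

Pearson correlations carry two-sided p-values from the t transform with
n − 2 df. PCA is performed on the **correlation** matrix, not the
covariance matrix: the activity variables mix units (mg/g contents,
mg/mL IC50s), and correlation PCA gives the interpretable
"eigenvalues sum to the number of variables" scale. Component signs are
fixed deterministically (the largest-magnitude loading of each component is
made positive). Hierarchical clustering standardizes variables to z-scores
before Euclidean distances — making results invariant to affine rescaling
of any variable — and defaults to Ward linkage (`hclust` "ward.D2",
Ward's criterion on proper Euclidean distances). Merge tie-breaks follow
`hclust`'s input-order convention; for the packaged data no ties arise.
Trees export to Newick via `ape`.

The packaged activity matrix deserves a caveat: the original comparison of
seven extraction methods is only partially printed (a handful of IC50s and
the TPC/TFC orderings), so `inst/extdata/activity_matrix_synthetic.csv` is
a **synthetic reconstruction** that honours every printed value and
ordering while interpolating the rest. Tests against it check qualitative
structure (which correlations are significant, which samples cluster
together) — they do not validate the unprinted quantitative values, and the
published PCA eigenvalues are therefore checked only loosely. The PCA and
clustering code itself is validated on closed-form cases (2×2 correlation
spectra, equicorrelation eigenstructure) and on synthetic matrices with
known latent correlation.

## Mass and neutral-loss arithmetic

Deprotonated m/z is the sum of IUPAC monoisotopic atomic masses minus the
**hydrogen atom** mass (1.007825). The physically stricter convention —
subtract a proton, keep the electron — differs by 0.00055 and is available
via `convention = "proton"`; the hydrogen-atom convention is the default
because it is what common deconvolution software prints in
"calculated mass" columns, and it reproduces the packaged peak table's
calculated masses to ≤ 0.0006 Da on all 67 rows. Neutral-loss annotation
matches precursor-to-fragment and fragment-to-fragment differences against
a library of diagnostic losses (hexose 162.0528, deoxyhexose 146.0579,
pentose 132.0423, galloyl 152.0110, water, CO, ketene, CO₂, SO₃, cross-ring
cleavages) with a default tolerance of 0.05 Da, chosen because the packaged
fragment m/z are printed to two decimals. Unmatched differences are
reported numerically rather than dropped.

Eight rows of the packaged peak table were curated where the printed
formula or calculated mass was arithmetically impossible (e.g. a formula
duplicated from a neighbouring row, a digit-transposed mass); the
as-printed value is preserved in the `cm_printed` column and the curation
is confined to the fixture — the mass code never special-cases them.
Compound names and confidence levels are fixture metadata; the package does
no identity assignment.

## Synthetic generators and what the tests show

All generators are pure functions of their parameters and an explicit seed
(the global RNG stream is left untouched). They emulate exactly the
structure each stage assumes: CCD responses as a known quadratic surface
plus i.i.d. Gaussian noise; dose-response as a 4PL curve plus Gaussian
noise; activity matrices as a single latent factor with loading √ρ giving
equicorrelation ρ. Gaussian noise throughout is a modelling choice
(replicate SDs in this field are routinely reported as symmetric mean ± sd;
nothing heavier-tailed is observable from such summaries).

Parameter-recovery tests close the loop for every stage: noise-free
simulations must be recovered exactly (OLS interpolation identity),
and noisy ones without systematic bias — linear-coefficient bias under
σ = 0.5 over 200 seeded simulations of the 20-run design, IC50 bias under
5% noise over 100 replicates, and the equicorrelation eigenvalue for PCA.
These sizes keep the full suite in tens of seconds while leaving Monte
Carlo error an order of magnitude below the asserted bounds. Passing them
shows the estimators are correct under the assumed noise model; it does
not certify behaviour under heteroscedastic or correlated errors, which
real plate readers and extractions can produce.

## Known limitations

* The packaged run table reproduces the published TFC model exactly, and
  the published TPC model in all independently verifiable coefficients
  except the temperature linear term: the data (including the published
  predicted values at the two temperature-axial runs, (22.89 − 9.64)/4 =
  3.3125) imply 3.3125 where 3.06 was printed. The package reports what the
  data imply; the TPC model F and adequate precision inherit this
  discrepancy, and the tests characterize rather than chase the printed
  values. The printed TPC intercept (23.39) similarly conflicts with the
  centre-run prediction (23.34).
* Desirability optimization is single-objective (the composite D); no
  Pareto front, and no propagation of prediction uncertainty into D.
* The annotation module does mass arithmetic only — no isotope patterns,
  no spectral library search, no structure elucidation.
* Backward elimination inherits the usual caveats of stepwise selection;
  it is provided because it is the field's reporting convention, with the
  full model always available.
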