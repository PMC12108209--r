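---
title: "From roGFP2 fluorescence ratios to redox potentials: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From roGFP2 fluorescence ratios to redox potentials: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rogfp2)
```

## The measurement chain

`rogfp2` implements the quantitative chain from raw two-channel
fluorescence to a glutathione redox potential, plus the statistics layer a
genotype-panel phenotyping study needs. The chain is:

1. **ROI intensities.** Mean pixel intensity of each excitation channel
   (405 nm, 488 nm) inside a circular region of interest, minus a
   background estimate, floored at zero.
2. **Ratio.** R = I405 / I488 from the background-corrected means.
3. **Degree of oxidation.** OxD from R and the calibration endpoints
   (fully reduced sensor in DTT, fully oxidized in H2O2).
4. **Redox potential.** E_GSH from OxD via the Nernst equation.

Each step is exposed on its own (`roi_mean()`, `ratio_measurement()`,
`compute_oxd()`, `egsh_from_oxd()`) and as compositions
(`egsh_from_intensities()`, `measure_stack_set()`, `run_redox_table()`).
The composite is tested to equal the stepwise path exactly.

### Assumptions

* The sensor equilibrates with the glutathione couple (in vivo this is
  ensured by a fused glutaredoxin); E_GSH is meaningful only under that
  assumption.
* Calibration images share the acquisition settings of the sample images:
  the same detector gains must apply to R_red, R_ox and R.
* ROIs are placed by the user (as in a manual microscopy workflow); the
  package performs no segmentation.

## Nernst constants

`rogfp_constants()` carries E0 = −272 mV, R = 8.315 J K⁻¹ mol⁻¹,
T = 298.15 K, z = 2, F = 96485 C mol⁻¹ and derives the slope
1000·ln(10)·R·T/(zF) ≈ 29.58 mV/decade. Two deliberate choices:

* **Temperature.** The conventional roGFP2 midpoint is quoted at 30 °C
  while the temperature constant used alongside it is 298.15 K (25 °C).
  The package uses both printed values verbatim, because that is the
  convention redox-imaging results are reported in; both are plain
  arguments, so a user who prefers a consistent 303.15 K can set it (the
  slope scales linearly with T, ≈0.5 mV/decade difference).
* **The log factor.** The decade slope uses ln(10) = 2.303 to convert the
  natural-log Nernst form to log10; this is fixed by dimensional analysis
  and by the requirement that OxD = 0.5 maps to exactly E0.

## The OxD formula and its intensity factor

`compute_oxd()` evaluates

OxD = (R − R_red) / [ (I488_red/I488_ox)·(R_ox − R) + (R − R_red) ].

The intensity factor corrects for the 488-excited brightness difference
between the reduced and oxidized sensor. Both orientations of that factor
satisfy the endpoint conditions OxD(R_red) = 0, OxD(R_ox) = 1, and both
appear in the literature; the package defaults to I488_red/I488_ox and
offers the reciprocal behind `i488_factor = "ox_over_red"`. Between the
endpoints the two differ, so the choice matters for absolute OxD values —
the default is the reading under which the synthetic-generator round trip
and the published-value inversions are self-consistent.

Noise can push a measured ratio outside [R_red, R_ox]. Erroring out would
kill batch runs on a single bad ROI, so out-of-range ratios are **clamped
to the nearest endpoint and flagged** (`"clamped"` attribute, carried into
result tables). Likewise OxD is clamped into [ε, 1−ε] (default ε = 10⁻⁶)
before the logarithm; ε is configurable and `clamp = FALSE` restores
strict domain errors.

## ROI quantification choices

The microscopy conventions a published intensity number depends on are
rarely written down; these are the package's explicit choices:

* **Pixel membership**: a pixel belongs to the ROI when its *center* lies
  inside the circle (pixel (i, j) centered at ((j−½)px, (i−½)px) µm).
  This rule is trivially enumerable, which is how the tests check it
  (brute-force pixel loops), and its pixelation error in the ROI area is
  below 5% for radii ≥ 10 px.
* **Ratio convention**: ratio of background-corrected ROI means, not the
  mean of per-pixel ratios. The ratio of means is robust where the 488
  signal is weak (single dim pixels do not blow up); a `"pixelwise"` mode
  exists for comparison, and a property test documents that the two agree
  exactly on uniform fields and diverge (Jensen's inequality) on
  gradients.
* **Background**: the mean of a user-designated background ROI (per image
  and channel in `quantify_rois()`), default 0. The *mean* is floored at
  zero rather than flooring individual pixels — per-pixel flooring would
  break the invariance of the result under adding a constant to both image
  and background, which the ratio step relies on.
* **Saturation**: pixels at or above a user-given level are excluded from
  means and flagged, since saturation biases ratios asymmetrically.
* **Units**: ROI geometry is specified in micrometers and converted via
  the stack's pixel size; potentials are reported in mV, rounded to 2
  decimals only in output tables, never internally.

## The synthetic generator

`biosensor_scene()` + `generate_biosensor_stack()` emulate what the
imaging experiment provides: a two-channel sample stack and matched
DTT/H2O2 calibration stacks. The sensor intensity model is the minimal one
consistent with the OxD formula: I488 interpolates linearly between the
endpoint intensities, and I405 = R(OxD)·I488 where R(OxD) is the exact
inverse of the OxD formula. Consequently the measurement chain inverts a
zero-noise scene *exactly* (to float-TIFF precision, ~10⁻⁷, when going
through files), which pins down sign and orientation conventions across
the whole pipeline.

The noise model is Poisson shot noise (default 400 photons per intensity
unit, i.e. low-hundreds of photons at typical signal levels — moderate
confocal illumination) plus Gaussian read noise (sd 0.005 a.u.). What the
generator does **not** emulate: optical blur, autofluorescence, spectral
bleed-through, pH sensitivity of the chromophore, photobleaching, or any
tissue geometry. Passing the recovery tests therefore shows the
*quantification chain* is unbiased under realistic counting noise, not
that real images are free of those systematic effects.

`generate_phenotype_table()` draws per-group trait vectors from a
multivariate normal with a target correlation matrix (Cholesky factor,
seeded), applies group mean shifts, and converts the lateral-root count by
rounding and flooring a Gaussian-copula coordinate — this preserves the
correlation structure the downstream analysis consumes, which a Poisson
regression would distort. A non-positive-semidefinite target correlation
is an error, never silently repaired. `phenotype_preset_gpxl()` encodes a
nine-genotype × five-treatment design, 45 seedlings per group, with
illustrative effect sizes (salt/osmotic stress raising ROS tens of percent
to ~2-fold and halving vitality; mutants with elevated shoot ROS) and a
two-factor trait correlation (oxidative load, vigor) in which shoot-root
vitality correlate at 0.81 within groups and ROS-vitality at about −0.49;
pooling treatments within a genotype strengthens these through the shared
treatment response, as in the real analysis design. The per-genotype
variants (ROS-lateral-root coupling absent in gpxl1/5/7, strengthened in
gpxl4/6/8) exercise the per-genotype correlation panels.

## Duncan's multiple range test

After a one-way ANOVA (`stats::aov` behind `anova_oneway()`), means are
sorted and a span of p consecutive ordered means is tested against the
critical range q_p·√(MSE/n), where q_p is the studentized-range quantile
at Duncan's protection level 1 − (1−α)^(p−1) — computed numerically
(`qtukey`, with a root-finding fallback on `ptukey` for wide spans where
`qtukey`'s inversion fails) rather than read from printed tables, so any
error df is supported. At p = 2 the level is exactly α, so adjacent-mean
comparisons are never more conservative than an unprotected range test.

Decisions respect **containment**: a span is non-significant if any
enclosing span is. Letters are assigned by insert-and-absorb over the
maximal non-significant spans, with ties in means broken by group label
order for deterministic output; the letter display reconstructs the
pairwise decision set exactly (tested against a brute-force oracle that
enumerates every span independently). Unbalanced groups use the harmonic
mean of group sizes in the critical range and set a warning flag — the
intended designs are near-balanced, and the harmonic-mean correction is
the standard small-imbalance treatment. Degenerate input (all observations
identical) reports F as undefined and one shared letter.

No correction is applied **across** traits or figures: the test controls
comparisons within one trait only, matching how such panels are
conventionally reported. Pearson matrices (`pearson_matrix()`) mark cells
with fewer than 3 pairs or zero variance as undefined (`NA`), not 0, and
by default pool all treatment conditions within a genotype — the treatment
response is part of the biological variation the correlation is meant to
capture; pass a pre-filtered table to correlate within a single condition.

## Problem sizes and numerics

The test suite and acceptance script run entirely on synthetic data:
48-64 px square scenes (ROI covering ~90% of the short dimension), 200
Monte-Carlo scenes for the bias check, 100 random instances for the Duncan
oracle, and 45 seedlings per simulated group — sizes chosen to estimate
each quantity to well within its tolerance while keeping a full run in
seconds. Numerical tie-breaks worth knowing: OxD at R = R_red is defined
as exactly 0 (the 0/0 limit), stack intensities are [0, 1] floats (the
storage contract of 32-bit float TIFF), and all generators consume one
seed and are bit-reproducible given it.

## Known limitations

* Absolute OxD depends on the intensity-factor orientation (above);
  cross-study comparisons should state the convention.
* E_GSH assumes sensor-glutathione equilibrium and the stated constants;
  no pH correction is applied.
* The image layer quantifies given ROIs only — no registration,
  deconvolution or meristem detection.
* Duncan's test does not control the familywise error rate at α for
  k > 2; it is implemented because it is the convention of this assay
  family, not as a recommendation.
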