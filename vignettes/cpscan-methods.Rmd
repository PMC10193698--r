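---
title: "Carbon particle quantification and study inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon particle quantification and study inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpscan)
```

## The measurement problem

Combustion-derived carbon particles emit broadband ("white") light under
femtosecond pulsed illumination. Two properties distinguish them from
everything else in a label-free tissue scan: the emission *saturates* the
detector relative to endogenous signals, and it spans the whole visible
spectrum, so a genuine particle appears simultaneously in a narrow
second-harmonic detection band (405/10 nm, otherwise dominated by collagen)
and a broad autofluorescence band (550/200 nm, dominated by tissue). cpscan
implements the resulting caller: threshold each channel at a fraction of its
own per-tile maximum (99.5% narrow, 55% broad), intersect the two masks, and
count connected components of the intersection. Counts are normalised by the
segmented tissue area and the physical section thickness (7 µm) to a
volumetric load in particles/mm³.

The statistical layer mirrors a two-group gestational inhalation study in a
species with a haemodichorial placenta: 7 dams per group, about 4 fetuses
per dam, six compartments (placenta, heart, kidney, liver, lung, gonads).
Fetus-level loads are pooled per litter after an exchangeability check, the
dam is the inferential unit, and group contrasts use exact small-sample
rank tests. Organ weights and weight ratios are related to log10 load with
dam-level mixed models, and a multiple factor analysis (MFA) summarises
loads, weights and ratios jointly.

## The synthetic study generator

Raw tile scans of this kind are rarely distributable, so the package
ships a generator whose ground truth embodies the effect structure the
design targets; every stage is tested by recovering that truth.

**Density hierarchy.** Mean densities are parametrised by the exposed
placental mean and two effect vectors: per-organ
exposed:control fold-changes (4.1, 3.3, 2.6, 1.9, 1.8 for placenta, heart,
kidney, liver, lung) and per-organ deficits of the exposed organs relative
to the placenta (0.15, 0.25, 0.55, 0.61, 0.72 for heart, kidney, liver,
lung, gonads). Control means are *derived* as exposed/fold, so both effect
families hold exactly by construction. Individual sample densities are
lognormal: a mean-corrected dam factor shared by all organs of a litter
(inducing the positive between-organ litter correlations seen in such data)
times an independent fetus-by-organ factor.

**Calibrated variability and the gonad fold-change.** The design targets a
specific significance pattern at n = 7 litters per group: every organ
significant (lung at p < 0.01) except the gonads. That pattern constrains
the plausible litter-level variability, and we fixed the generator's
defaults by a design-stage power calculation *before* wiring up any
end-to-end test: with `dam_sd_log = 0.25` and `fetus_sd_log = 0.25` the
exact Mann-Whitney test detects the lung effect (fold 1.8) and the liver
effect (fold 1.9) in well over 80% of simulated studies. At that
variability a gonad fold of 1.3 — a value sometimes suggested as a "small,
non-significant" effect — is rejected in substantially more than 20% of
studies, contradicting the non-significance it is meant to encode; the
default is therefore 1.15, which keeps the gonad rejection rate well below
20% (the thresholds the significance-pattern test asserts). These defaults
are the package's definition of the study conditions and are not tuned
afterwards.

**Absolute scale.** The design fixes relative effects, not absolute
densities. The default
control placental density is 2.5×10⁴ particles/mm³ — the order of magnitude
published for label-free carbon detection in human placenta — and, equally
importantly, it puts the fractional-of-maximum caller in its intended
regime: the thresholds are fractions of the *per-tile maximum*, which is
only meaningful when particles (which saturate) set that maximum. The
method presumes particles are present in essentially every imaged region
(in practice even control tissues carry a background burden); at the
default density the expected
per-tile count at desk scale is ≥ 4 and particle-free tiles are rare
(~1–2%). In a particle-free tile the brightest collagen pixel defines the
narrow maximum and produces on the order of one spurious call — an honest
property of the method, and a negligible (<1%) contribution at the default
densities.

**Image formation.** The broad channel is a textured tissue background
(multiplicative smooth field, ±35%) restricted to a smooth tissue blob
covering a configurable fraction of the tile (default 0.85, area made exact
by choosing the blob radius as the corresponding quantile of the radial
coordinate); the narrow channel is dark except for sparse curvilinear
collagen structures capped at 85% of saturation so they can never pass the
99.5% threshold once a particle saturates the channel. Particles are
Gaussian spots (σ = 1 px) with pre-clip peaks at 5× saturation added to
*both* channels, so their cores clip at the detector maximum. Noise is
Poisson shot noise plus Gaussian read noise (σ = 3 counts); where the
expected count exceeds 12 the Poisson component is drawn from its
moment-matched normal limit folded with the read noise — at the background
level of 120 counts the approximation error is far below the quantisation
step — and counts are quantised to integers and clipped to [0, 4095].

**Biometry.** Weights are lognormal around the design medians (fetal 36 g,
placenta 7.4 g, heart 0.20 g, kidney 0.17 g, liver 2.4 g, lung 0.98 g) with
a 10% coefficient of variation; gonads are not weighed and stay `NA`. The
placenta/fetus weight ratio (×10 display scale) responds to the fetus's
log10 placental load with slope 0.46 per decade plus a dam-level random
intercept *and* a dam-level random slope (SD 0.10 per decade: litters
differ in how strongly their ratios track load, which is why the placental
model carries a random slope at all) — exactly the structure the mixed
model estimates, making slope recovery and confidence-interval coverage
testable.

**What the generator does not emulate.** No optics: no spectral emission
model, no depth-dependent attenuation, no tile-stitching artefacts, no
anisotropic PSF. No segmentation difficulty: real tissue sections have
folds, debris and intensity gradients that the smooth synthetic blob does
not reproduce, so passing tests demonstrate correctness of the *algorithms*
under the stated signal model, not robustness to every histological
artefact.

## Numerical and procedural choices

* **Connectivity.** "Connected pixels" is interpreted as 8-connectivity
  (diagonal neighbours merge), the safer choice for few-pixel saturated
  blobs; it is configurable, and one particle is one connected component —
  no sub-peak splitting, because the method counts thresholded overlapping
  pixels rather than resolved peaks.
* **Per-tile maxima.** Thresholds are fractions of each channel's maximum
  per tile scan (the acquisition unit), and all pixels tied at the maximum
  pass (`>=`).
* **Tissue segmentation.** The broad channel is block-downsampled, box-blur
  smoothed, and thresholded by Otsu's method *on the log intensity* —
  saturating particles inside tissue would otherwise dominate the
  between-class variance and flip the threshold to a particles-vs-tissue
  split. Morphological closing, hole filling and small-object removal
  follow. When no bimodal split exists the tile is all tissue or all
  background, told apart by a 20-count mean-level floor. On synthetic tiles
  the segmented area is within ~3% of truth; area errors cancel in
  fold-changes and deficits, which are ratios.
* **Region aggregation.** A sample's load is the unweighted mean of its
  region loads (default) or, optionally, pooled counts over pooled volume;
  regions with zero segmented area are excluded with a warning and samples
  with fewer than five usable regions are flagged.
* **Exact tests.** Mann-Whitney p-values enumerate all C(n+m, n) labelings
  when feasible (3432 at 7 vs 7), the signed-rank test enumerates 2ⁿ sign
  patterns, Spearman enumerates n! permutations up to n = 8; all use
  midranks and the symmetric two-sided rule. Beyond the enumeration budget
  they fall back to tie-corrected normal (or t) approximations and say so.
* **Pooling check.** Kruskal-Wallis across litters within group and organ,
  with hand-rolled Dunn z post-hocs (Bonferroni). The pooling verdict gates
  on the omnibus p as well as the pairwise minima, since fully adjusted
  pairwise tests alone have little power at four fetuses per litter.
* **Zeros before log10.** Replaced by half the smallest positive load, with
  the count reported; real samples always contained particles, so this only
  matters for tiny simulated tiles.
* **Mixed models.** `nlme::lme` by maximum likelihood (fixed effects
  comparable across organs; REML available), random intercept per dam, plus
  a random slope on log10 load for the placenta; a singular random-slope
  fit falls back to intercept-only and is flagged, never silently accepted.
  Wald 95% intervals.
* **Quartiles.** Linear interpolation (type 7), documented because
  median (Q1; Q3) displays depend on the convention.
* **MFA construction.** Columns are centred and scaled by *population* SD;
  each group's columns are weighted by 1/√λ₁ of the group's own PCA; the
  global SVD uses uniform weights 1/n. Individual coordinates have
  population variance λ_d per dimension; supplementary categories get
  barycentre coordinates, the finite-population v.test
  (√(n_k(n−1)/(n−n_k)) · barycentre/√λ_d), cos² across retained dimensions,
  one-way ANOVA R² per dimension, and 95% barycentre ellipses
  (covariance/n_k scaled by the χ²(2) quantile). Dimension signs are fixed
  by forcing the largest-|correlation| variable positive. Exposure and sex
  never influence the fit — they are projected post hoc. Loads enter the
  MFA on the log10 scale, consistent with the mixed models.

## Problem sizes of the shipped experiments

Simulation experiments in the test-suite and the reproduction script run at
a desk-scale geometry chosen by the package: 176-px tiles (0.83 µm pixels,
7 µm sections, five regions per sample) and 25 independent study replicates
for the end-to-end recovery experiments. Loads are defined per unit volume,
so their expectations are invariant to tile size; the native 4096-px
geometry and the 512-px default remain available through
`imaging_config()`. At desk scale the dominant recovery errors are particle
co-localisation (two particles closer than about twice the saturated core
radius merge into one component, an ~3% undercount at the exposed placental
density) and the ~1–2% of control tiles that contain no particle; both are
far inside the tolerances of the recovery experiments.

## Known limitations

* The caller is only defined when particles set the channel maxima;
  particle-free tiles yield on the order of one spurious call each, which
  matters at densities far below the defaults.
* Exact tests are conservative (discrete statistics); at 7 vs 7 the
  achievable two-sided levels jump, which the power statements above
  already reflect.
* The v.test treats retained dimensions only, and cos² is reported without
  an interpretation threshold.
* In the simulator the MFA's exposure contrast reliably loads on one of the
  two leading dimensions (both carry ~45–50% of inertia together), but not
  always dimension 1: the synthetic biometry contains a body-size
  correlation block (weights and their derived ratios share the fetal
  weight) whose eigenvalue competes with the load block's, and the ranking
  flips between seeds.
* No stereological correction for particle truncation at section faces is
  applied; loads are raw areal counts scaled to the section volume.
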