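# cpscan

Quantifying combustion-derived carbon particles in label-free two-channel
femtosecond-laser tile scans of placental and fetal tissue, and running the
full hierarchical exposure-study inference on the resulting loads.

Carbon particles emit broadband white light under femtosecond pulsed
illumination. Two signatures set them apart from endogenous signals: the
emission **saturates** the detector, and it spans the visible spectrum, so a
genuine particle is bright **simultaneously** in the narrow second-harmonic
channel (405/10 nm, otherwise collagen) and the broad autofluorescence
channel (550/200 nm, otherwise tissue). The caller thresholds each channel
at a fraction of its per-tile maximum — 99.5% (narrow) and 55% (broad) —
intersects the masks, and counts 8-connected components:

```
particle mask = {I_405 >= 0.995 * max(I_405)} AND {I_550 >= 0.55 * max(I_550)}
CP load [mm^-3] = n_components / (tissue area [mm^2] * 7 um section * 1e-3)
```

Downstream, the package implements the whole analysis battery of a
two-group gestational inhalation study (7 dams/group, ~4 fetuses/dam, six
compartments): litter pooling after a Kruskal-Wallis/Dunn exchangeability
check, exact Mann-Whitney / Wilcoxon signed-rank / Spearman tests (full
enumeration at study sizes), fold-changes and organ-vs-placenta deficits,
dam-level mixed-effects biometry models (`nlme`), and a from-scratch
multiple factor analysis (group-weighted PCA) with v.test, cos²,
dimension R² and 95% barycentre ellipses.

Because no raw data are distributable, the package ships a synthetic study
generator that renders two-channel tiles (textured autofluorescence,
collagen structures, saturating particle spots, shot + read noise) around a
known ground truth embodying the reported effect structure — placental
fold-change 4.1, heart 3.3, kidney 2.6, liver 1.9, lung 1.8; organ deficits
15–72% — so every stage is testable end to end.

## Worked example

```r
library(cpscan)

cfg <- run_config(seed = 1, imaging = imaging_config(tile_pixels = 176))
res <- run_pipeline(cfg)   # simulate -> render -> detect -> quantify -> infer
res
#> <cp_run> seed 1
#>
#> Fold changes (exposed/control):
#>   organ    fold_change  p_value
#> 1 placenta        3.92 0.000583
#> 2 heart           3.59 0.000583
#> 3 kidney          3.08 0.000583
#> 4 liver           2.02 0.00408
#> 5 lung            1.76 0.0111
#> 6 gonad           1.16 0.710
#>
#> Deficits vs placenta (exposed):
#>   organ  deficit p_value
#> 1 heart    0.133  0.0312
#> 2 kidney   0.189  0.0156
#> 3 liver    0.535  0.0156
#> 4 lung     0.611  0.0156
#> 5 gonad    0.704  0.0156
```

One seeded run of a full study (2 × 7 litters × 4 fetuses × 6 organs × 5
rendered regions). The fold-change table gives the exposed:control ratio of
group means of litter-mean loads with the exact Mann-Whitney p of the
litter-level comparison: every compartment shows a significant exposure
effect except the gonads, and single-seed estimates scatter around the
generating truth (4.1/3.3/2.6/1.9/1.8). The deficit table is the fraction
of the placental load not reaching each organ among exposed litters, with
exact paired Wilcoxon p-values. The MFA separates the exposure groups on
one of the two leading dimensions:

```r
res$mfa$exposure$categories[res$mfa$exposure$categories$dim %in% 1:2, ]
#>   level dim n_k  coord v_test  cos2 significant
#> 1     C   1  28  0.194   1.03 0.055       FALSE
#> 2     C   2  28 -0.415  -2.46 0.249        TRUE
#> 3    DE  1  28 -0.194  -1.03 0.055       FALSE
#> 4    DE  2  28  0.415   2.46 0.249        TRUE
```

`|v.test| > 1.96` flags a barycentre far outside its random-allocation
null; which of the two inertia-rich dimensions carries the exposure
contrast is seed-dependent in the simulator. Individual stages are plain
functions on tabular data — `render_tile()`, `call_particles()`,
`segment_tissue()`, `load_per_mm3()`, `pool_by_dam()`,
`mann_whitney_exact()`, `fit_lmm()`, `mfa()` — and fitted objects have
`tidy()`/`glance()`/`autoplot()` methods. A thin command-line driver lives
at `inst/scripts/cpscan.R`
(`cpscan.R simulate|detect|quantify|stats|run --config cfg.yaml`).

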