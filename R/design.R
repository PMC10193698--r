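#' The six fetoplacental compartments
#'
#' Ordered set of tissue compartments handled by the study design: the
#' placenta plus the five fetal organs that are dissected and imaged.
#'
#' @return Character vector of length six.
#' @export
cp_organs <- function() {
  c("placenta", "heart", "kidney", "liver", "lung", "gonad")
}

#' Study design for a two-group gestational exposure experiment
#'
#' Describes the hierarchical sampling structure: dams (litters) nested in
#' exposure groups, fetuses nested in dams, and one measurement per fetus and
#' organ. The litter is the statistical unit downstream, so
#' `n_dams_per_group` is the effective group size.
#'
#' @param n_dams_per_group Number of dams (litters) per exposure group.
#' @param n_fetuses_per_dam Number of fetuses sampled per dam.
#' @param sex_ratio Expected fraction of male fetuses.
#' @param groups Labels of the control and exposed group, in that order.
#' @return A `cp_design` list.
#' @export
study_design <- function(n_dams_per_group = 7,
                         n_fetuses_per_dam = 4,
                         sex_ratio = 0.5,
                         groups = c("C", "DE")) {
  stopifnot(n_dams_per_group >= 2, n_fetuses_per_dam >= 1,
            sex_ratio >= 0, sex_ratio <= 1, length(groups) == 2)
  structure(
    list(
      n_dams_per_group = as.integer(n_dams_per_group),
      n_fetuses_per_dam = as.integer(n_fetuses_per_dam),
      organs = cp_organs(),
      sex_ratio = sex_ratio,
      groups = as.character(groups)
    ),
    class = "cp_design"
  )
}

#' Organ-level effect profile of the exposure
#'
#' Parametrises the ground-truth particle densities of the simulated study.
#' The exposed-group mean density of each organ is derived from the exposed
#' placental mean (`placenta_control_density * fold_change["placenta"]`) and
#' the organ's deficit relative to the placenta; the control mean is then the
#' exposed mean divided by the organ's fold-change. Control means are
#' therefore derived quantities, never set independently, so fold-changes and
#' deficits are both exactly embodied by construction.
#'
#' Between-litter and within-litter biological variability are lognormal
#' multiplicative factors: a dam-level factor shared by all organs of a
#' litter (inducing positive between-organ correlation of litter means) and
#' an independent fetus-by-organ factor. Both are mean-corrected so expected
#' densities equal the configured means. The default standard deviations
#' (0.25 on the natural-log scale) were fixed by a design-stage power
#' analysis so that, at seven litters per group, the exposure effect is
#' detectable by an exact rank test for every organ except the gonads —
#' the significance pattern the design is meant to emulate. For the same
#' reason the default gonad fold-change is 1.15: the one organ intended to
#' stay below the detection threshold of the study size.
#'
#' @param placenta_control_density Mean control placental particle density,
#'   particles per mm^3 tissue.
#' @param fold_change Named vector, exposed/control density ratio per organ.
#' @param exposed_deficit_vs_placenta Named vector, fractional deficit of
#'   each fetal organ relative to the placenta within the exposed group.
#' @param dam_sd_log SD of the dam-level lognormal factor (log scale).
#' @param fetus_sd_log SD of the fetus-by-organ lognormal factor (log scale).
#' @param biometry Biometry generator parameters, see [biometry_profile()].
#' @return A `cp_effects` list.
#' @export
organ_effects <- function(placenta_control_density = 2.5e4,
                          fold_change = c(placenta = 4.1, heart = 3.3,
                                          kidney = 2.6, liver = 1.9,
                                          lung = 1.8, gonad = 1.15),
                          exposed_deficit_vs_placenta = c(placenta = 0,
                                                          heart = 0.15,
                                                          kidney = 0.25,
                                                          liver = 0.55,
                                                          lung = 0.61,
                                                          gonad = 0.72),
                          dam_sd_log = 0.25,
                          fetus_sd_log = 0.25,
                          biometry = biometry_profile()) {
  organs <- cp_organs()
  fold_change <- fold_change[organs]
  deficit <- exposed_deficit_vs_placenta[organs]
  if (anyNA(fold_change) || anyNA(deficit)) {
    stop("fold_change and exposed_deficit_vs_placenta must name all six organs",
         call. = FALSE)
  }
  stopifnot(placenta_control_density > 0, all(fold_change > 0),
            all(deficit >= 0), all(deficit < 1),
            dam_sd_log >= 0, fetus_sd_log >= 0)
  if (deficit[["placenta"]] != 0) {
    stop("the placental deficit relative to itself must be 0", call. = FALSE)
  }
  structure(
    list(
      placenta_control_density = placenta_control_density,
      fold_change = fold_change,
      exposed_deficit_vs_placenta = deficit,
      dam_sd_log = dam_sd_log,
      fetus_sd_log = fetus_sd_log,
      biometry = biometry
    ),
    class = "cp_effects"
  )
}

#' Biometry generator parameters
#'
#' Medians of fetal and organ weights (grams) and the structural link between
#' placental particle load and the placenta/fetus weight ratio. Weights are
#' drawn lognormally around their medians with coefficient of variation
#' `weight_cv`; gonads are not weighed (too small to dissect reliably), so
#' their weight is `NA` throughout. The weight ratio (x10 display scale)
#' responds linearly to log10 placental load with slope
#' `ratio_slope_per_decade`, i.e. the expected change in ratio per 10-fold
#' increase in load, plus a dam-level random intercept and residual noise —
#' the generating model matched by [fit_lmm()].
#'
#' @param fetal_weight_g Median fetal weight.
#' @param organ_weight_g Named medians for placenta-independent organs.
#' @param weight_cv Lognormal coefficient of variation of all weights.
#' @param sex_effect_log Additive log-scale effect of male sex on fetal weight.
#' @param ratio_intercept Median placenta/fetus weight ratio (x10 scale).
#' @param ratio_slope_per_decade Change in ratio (x10) per decade of
#'   placental particle load.
#' @param ratio_dam_sd SD of the dam-level random intercept on the ratio.
#' @param ratio_dam_slope_sd SD of the dam-level random slope (per decade of
#'   load) on the ratio — litters differ in how strongly their ratios track
#'   placental load, which is why the ratio model carries a random slope.
#' @param ratio_resid_sd Residual SD of the ratio.
#' @return A `cp_biometry_profile` list.
#' @export
biometry_profile <- function(fetal_weight_g = 36,
                             organ_weight_g = c(heart = 0.20, kidney = 0.17,
                                                liver = 2.4, lung = 0.98),
                             weight_cv = 0.10,
                             sex_effect_log = 0.04,
                             ratio_intercept = 2.1,
                             ratio_slope_per_decade = 0.46,
                             ratio_dam_sd = 0.15,
                             ratio_dam_slope_sd = 0.10,
                             ratio_resid_sd = 0.35) {
  stopifnot(fetal_weight_g > 0, all(organ_weight_g > 0), weight_cv >= 0,
            ratio_intercept > 0, ratio_dam_sd >= 0, ratio_resid_sd >= 0)
  structure(
    list(
      fetal_weight_g = fetal_weight_g,
      organ_weight_g = organ_weight_g,
      weight_cv = weight_cv,
      sex_effect_log = sex_effect_log,
      ratio_intercept = ratio_intercept,
      ratio_slope_per_decade = ratio_slope_per_decade,
      ratio_dam_sd = ratio_dam_sd,
      ratio_dam_slope_sd = ratio_dam_slope_sd,
      ratio_resid_sd = ratio_resid_sd
    ),
    class = "cp_biometry_profile"
  )
}

#' Imaging geometry and signal model of the simulated tile scans
#'
#' Captures the acquisition geometry (tile edge in pixels, pixel size,
#' physical section thickness, regions imaged per sample) and the signal
#' parameters of the two detection channels: a broad autofluorescence channel
#' with a textured tissue background and a narrow second-harmonic channel
#' that is dark except for sparse collagen structures. Carbon particles are
#' rendered into *both* channels as point-spread blurred spots whose peak
#' exceeds the detector maximum by `particle_peak_factor`, so their cores
#' clip at `saturation_level` — the co-channel saturation property that the
#' particle caller exploits.
#'
#' @param tile_pixels Edge length of a (square) tile in pixels. The native
#'   acquisition is 4096; the default 512 keeps simulated studies desk-scale,
#'   and densities are per volume so results are size-invariant.
#' @param pixel_size_um Pixel size in micrometres.
#' @param section_thickness_um Physical section thickness in micrometres.
#' @param n_regions_per_sample Tissue regions imaged per sample.
#' @param psf_sigma_px Lateral Gaussian point-spread SD of a particle, pixels.
#' @param saturation_level Detector maximum (counts).
#' @param particle_peak_factor Pre-clip particle peak, multiples of saturation.
#' @param broad_background Mean tissue autofluorescence level (counts).
#' @param narrow_background Mean narrow-channel background level (counts).
#' @param dark_level Broad-channel level outside tissue (counts).
#' @param read_noise_sd Gaussian read noise SD (counts).
#' @param texture_amp Relative amplitude of the autofluorescence texture.
#' @param texture_scale_px Correlation length of the texture, pixels.
#' @param collagen_per_mm2 Expected number of collagen structures per mm^2.
#' @param collagen_peak Typical collagen peak intensity (counts); kept well
#'   below saturation so collagen never co-saturates the broad channel.
#' @param z_slice_um Optical slice spacing of z-stacks, micrometres.
#' @param z_n_slices Default number of slices in a rendered z-stack.
#' @return A `cp_imaging` list.
#' @export
imaging_config <- function(tile_pixels = 512,
                           pixel_size_um = 0.83,
                           section_thickness_um = 7,
                           n_regions_per_sample = 5,
                           psf_sigma_px = 1.0,
                           saturation_level = 4095,
                           particle_peak_factor = 5,
                           broad_background = 120,
                           narrow_background = 3,
                           dark_level = 4,
                           read_noise_sd = 3,
                           texture_amp = 0.35,
                           texture_scale_px = 24,
                           collagen_per_mm2 = 20,
                           collagen_peak = 1200,
                           z_slice_um = 0.63,
                           z_n_slices = 12) {
  stopifnot(tile_pixels >= 16, pixel_size_um > 0, section_thickness_um > 0,
            n_regions_per_sample >= 1, psf_sigma_px > 0,
            saturation_level > broad_background,
            saturation_level > dark_level,
            particle_peak_factor > 1,
            read_noise_sd >= 0, z_slice_um > 0, z_n_slices >= 3,
            collagen_peak < saturation_level)
  structure(
    list(
      tile_pixels = as.integer(tile_pixels),
      pixel_size_um = pixel_size_um,
      section_thickness_um = section_thickness_um,
      n_regions_per_sample = as.integer(n_regions_per_sample),
      psf_sigma_px = psf_sigma_px,
      saturation_level = saturation_level,
      particle_peak_factor = particle_peak_factor,
      broad_background = broad_background,
      narrow_background = narrow_background,
      dark_level = dark_level,
      read_noise_sd = read_noise_sd,
      texture_amp = texture_amp,
      texture_scale_px = texture_scale_px,
      collagen_per_mm2 = collagen_per_mm2,
      collagen_peak = collagen_peak,
      z_slice_um = z_slice_um,
      z_n_slices = as.integer(z_n_slices)
    ),
    class = "cp_imaging"
  )
}

#' Particle caller parameters
#'
#' Fractions of the per-tile channel maxima used as detection thresholds:
#' 99.5% of the narrow-channel maximum and 55% of the broad-channel maximum.
#' A pixel is particle candidate only when it exceeds both thresholds, and
#' candidates are grouped into particles as connected components.
#'
#' @param narrow_fraction Fraction of the narrow-channel maximum.
#' @param broad_fraction Fraction of the broad-channel maximum.
#' @param connectivity Pixel connectivity, 8 (default) or 4.
#' @param min_component_px Minimum component size, pixels.
#' @return A `cp_detection_params` list.
#' @export
detection_params <- function(narrow_fraction = 0.995,
                             broad_fraction = 0.55,
                             connectivity = 8,
                             min_component_px = 1) {
  stopifnot(narrow_fraction > 0, narrow_fraction <= 1,
            broad_fraction > 0, broad_fraction <= 1,
            connectivity %in% c(4, 8), min_component_px >= 1)
  structure(
    list(
      narrow_fraction = narrow_fraction,
      broad_fraction = broad_fraction,
      connectivity = as.integer(connectivity),
      min_component_px = as.integer(min_component_px)
    ),
    class = "cp_detection_params"
  )
}

#' Ground-truth mean particle density per organ and group
#'
#' Expands an effect profile into the mean density (particles/mm^3) of each
#' organ in each group. Exposed means derive from the exposed placental mean
#' and the per-organ deficit; control means are exposed means divided by the
#' fold-change.
#'
#' @param effects A [organ_effects()] profile.
#' @param design A [study_design()] (for group labels).
#' @return Tibble with columns `organ`, `group`, `mean_density`.
#' @export
organ_mean_density <- function(effects = organ_effects(),
                               design = study_design()) {
  organs <- cp_organs()
  exposed_placenta <- effects$placenta_control_density *
    effects$fold_change[["placenta"]]
  exposed <- exposed_placenta * (1 - effects$exposed_deficit_vs_placenta)
  control <- exposed / effects$fold_change
  tibble::tibble(
    organ = rep(organs, 2),
    group = rep(design$groups, each = length(organs)),
    mean_density = c(unname(control[organs]), unname(exposed[organs]))
  )
}
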