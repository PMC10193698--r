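#' Measure a simulated study through the full imaging pipeline
#'
#' For every fetus-by-organ sample of a simulated study, renders
#' `n_regions_per_sample` tissue regions at the sample's true particle
#' density, runs the particle caller and the tissue segmentation on each
#' rendered tile, converts counts to volumetric loads and averages regions
#' into the sample load. This is the measured (image-derived) counterpart of
#' the ground-truth densities in `sim$study`.
#'
#' @param sim A [simulate_study()] result.
#' @param params A [detection_params()].
#' @param tissue_fraction Tissue coverage of each rendered tile.
#' @param noise Render with noise (default `TRUE`).
#' @param outdir Optional directory: tiles, sidecars and a manifest CSV are
#'   written there (slow; meant for small studies and the command line).
#' @return List: `study` (fetus-level tibble with measured `cp_load` and
#'   `true_density`), `regions` (per-region detail), `manifest_path`.
#' @export
measure_study <- function(sim, params = detection_params(),
                          tissue_fraction = 0.85, noise = TRUE,
                          outdir = NULL) {
  stopifnot(inherits(sim, "cp_sim"))
  imaging <- sim$imaging
  thick_mm <- imaging$section_thickness_um * 1e-3
  px_mm <- imaging$pixel_size_um * 1e-3
  n_regions <- imaging$n_regions_per_sample
  rows <- nrow(sim$study)
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  sample_load <- numeric(rows)
  region_rows <- vector("list", rows)
  manifest <- if (!is.null(outdir)) vector("list", rows) else NULL

  for (i in seq_len(rows)) {
    s <- sim$study[i, ]
    sample_id <- paste(s$fetus_id, s$organ, sep = "_")
    loads <- numeric(n_regions)
    counts <- integer(n_regions)
    areas <- numeric(n_regions)
    planted <- integer(n_regions)
    true_areas <- numeric(n_regions)
    paths <- character(n_regions)
    for (r in seq_len(n_regions)) {
      mask <- make_tissue_mask(imaging$tile_pixels, tissue_fraction)
      true_area <- sum(mask) * px_mm^2
      n_true <- stats::rpois(1, s$true_density * true_area * thick_mm)
      if (n_true > 0) {
        idx <- sample(which(mask), n_true, replace = TRUE)
        nr <- nrow(mask)
        cent <- cbind(((idx - 1) %% nr) + 1 + stats::runif(n_true, -0.49, 0.49),
                      ((idx - 1) %/% nr) + 1 + stats::runif(n_true, -0.49, 0.49))
      } else {
        cent <- matrix(numeric(0), 0, 2)
      }
      tile <- render_tile(cent, imaging, mask = mask, noise = noise,
                          sample_id = sample_id, region_id = r)
      calls <- call_particles(tile, params)
      seg <- segment_tissue(tile)
      area <- attr(seg, "area_mm2")
      counts[r] <- calls$n
      areas[r] <- area
      planted[r] <- n_true
      true_areas[r] <- true_area
      loads[r] <- if (area > 0) load_per_mm3(calls$n, area,
                                             imaging$section_thickness_um)
                  else NA_real_
      if (!is.null(outdir)) {
        paths[r] <- file.path(outdir, paste0(sample_id, "_r", r, ".tiff"))
        write_tile(tile, paths[r])
      }
    }
    agg <- suppressWarnings(aggregate_sample(loads, n_min = n_regions))
    sample_load[i] <- agg$sample_load
    region_rows[[i]] <- tibble::tibble(
      fetus_id = s$fetus_id, organ = as.character(s$organ),
      region_id = seq_len(n_regions),
      n_particles = counts, n_planted = planted,
      area_mm2 = areas, true_area_mm2 = true_areas, load = loads,
      image_path = if (!is.null(outdir)) paths else NA_character_
    )
  }

  study <- sim$study
  study$cp_load <- sample_load
  regions <- dplyr::bind_rows(region_rows)
  manifest_path <- NULL
  if (!is.null(outdir)) {
    manifest_path <- file.path(outdir, "manifest.csv")
    man <- dplyr::left_join(
      regions,
      study[, c("fetus_id", "organ", "dam_id", "group", "sex",
                "true_density", "fetal_weight_g")] |>
        dplyr::mutate(organ = as.character(.data$organ)),
      by = c("fetus_id", "organ"))
    utils::write.csv(man, manifest_path, row.names = FALSE)
  }
  list(study = study, regions = regions, manifest_path = manifest_path)
}

#' Run one complete simulated study end to end
#'
#' Convenience driver: seeds the generator, simulates the ground truth,
#' measures it through rendering, detection and quantification, and pools
#' the measured loads per litter.
#'
#' @param seed Integer seed (fully determines the run).
#' @param design,effects,imaging,params Configuration objects.
#' @param tissue_fraction Tissue coverage per tile.
#' @return List: `sim`, `study` (measured fetus-level), `litter` (pooled).
#' @export
run_study <- function(seed, design = study_design(),
                      effects = organ_effects(),
                      imaging = imaging_config(),
                      params = detection_params(),
                      tissue_fraction = 0.85) {
  sim <- simulate_study(design, effects, imaging, seed = seed)
  meas <- measure_study(sim, params, tissue_fraction = tissue_fraction)
  litter <- pool_by_dam(meas$study)
  list(sim = sim, study = meas$study, regions = meas$regions, litter = litter)
}

#' Pipeline run configuration
#'
#' Bundles every stage's parameters plus the seed into one serialisable
#' object; a run's config and seed fully determine its outputs.
#'
#' @param seed Integer seed.
#' @param design,effects,imaging,detection Stage configurations.
#' @param fold_stat Fold-change statistic, `"mean"` or `"median"`.
#' @param tissue_fraction Tissue coverage of rendered tiles.
#' @param mfa_factors Supplementary factors for the MFA: `"exposure"` and
#'   optionally `"exposure_sex"`.
#' @return A `cp_run_config` list.
#' @export
run_config <- function(seed = 1,
                       design = study_design(),
                       effects = organ_effects(),
                       imaging = imaging_config(),
                       detection = detection_params(),
                       fold_stat = "mean",
                       tissue_fraction = 0.85,
                       mfa_factors = c("exposure", "exposure_sex")) {
  structure(
    list(seed = as.integer(seed), design = design, effects = effects,
         imaging = imaging, detection = detection, fold_stat = fold_stat,
         tissue_fraction = tissue_fraction, mfa_factors = mfa_factors),
    class = "cp_run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a `cp_run_config`.
#' @export
write_run_config <- function(config, path) {
  # named atomic vectors become YAML maps (plain vectors would lose names)
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(strip(unclass(config)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_named <- function(x) if (is.list(x)) unlist(x) else x
  run_config(
    seed = y$seed %||% 1,
    design = do.call(study_design, lapply(y$design %||% list(), as_named)[
      intersect(names(y$design), names(formals(study_design)))]),
    effects = {
      e <- lapply(y$effects %||% list(), as_named)
      e <- e[intersect(names(e), names(formals(organ_effects)))]
      if (!is.null(e$biometry)) {
        b <- lapply(e$biometry, as_named)
        e$biometry <- do.call(biometry_profile,
                              b[intersect(names(b),
                                          names(formals(biometry_profile)))])
      }
      do.call(organ_effects, e)
    },
    imaging = do.call(imaging_config, lapply(y$imaging %||% list(), as_named)[
      intersect(names(y$imaging), names(formals(imaging_config)))]),
    detection = do.call(detection_params, (y$detection %||% list())[
      intersect(names(y$detection), names(formals(detection_params)))]),
    fold_stat = y$fold_stat %||% "mean",
    tissue_fraction = y$tissue_fraction %||% 0.85,
    mfa_factors = y$mfa_factors %||% c("exposure", "exposure_sex")
  )
}

#' Run the full analysis pipeline
#'
#' Chains simulate, render, detect, quantify, pool and the inference battery
#' (group comparisons, fold-changes, deficits, correlation matrix,
#' within-litter check, biometry mixed models, MFA with supplementary
#' factors) into one reproducible run. With an `outdir`, tables are written
#' as CSV and the headline numbers as a machine-readable JSON; identical
#' config and seed give byte-identical JSON.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory.
#' @return A `cp_run` list with every stage's result.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "cp_run_config"))
  stage <- "simulate+measure"
  res <- tryCatch({
    run <- run_study(config$seed, config$design, config$effects,
                     config$imaging, config$detection,
                     config$tissue_fraction)
    stage <- "stats"
    litter <- run$litter
    folds <- fold_changes(litter, config$fold_stat)
    deficits <- organ_deficits(litter)
    comparison <- group_comparison(litter)
    correlation <- cp_correlation(litter,
                                  group = config$design$groups[2])
    wl <- within_litter_check(run$study)
    stage <- "biometry"
    fetuses <- derive_biometry(run$sim$fetuses)
    lmm <- biometry_models(run$study, fetuses)
    stage <- "mfa"
    mfa_in <- study_mfa_input(run$study, fetuses)
    fit <- mfa(mfa_in$data, mfa_in$groups)
    mfa_res <- list(fit = fit)
    for (f in config$mfa_factors) {
      fac <- mfa_in[[f]]
      if (!is.null(fac)) {
        mfa_res[[f]] <- list(
          categories = supplementary_categories(fit, fac),
          dims = dimension_description(fit, fac, dims = 1:2)
        )
      }
    }
    list(run = run, litter = litter, fold_changes = folds,
         organ_deficits = deficits, group_comparison = comparison,
         correlation = correlation, within_litter = wl,
         biometry_models = lmm, mfa = mfa_res, config = config)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$run$study, file.path(outdir, "study.csv"),
                     row.names = FALSE)
    utils::write.csv(res$litter, file.path(outdir, "litter.csv"),
                     row.names = FALSE)
    utils::write.csv(res$fold_changes, file.path(outdir, "fold_changes.csv"),
                     row.names = FALSE)
    utils::write.csv(res$organ_deficits, file.path(outdir, "deficits.csv"),
                     row.names = FALSE)
    utils::write.csv(attr(res$correlation, "matrix"),
                     file.path(outdir, "spearman_matrix.csv"))
    utils::write.csv(res$biometry_models, file.path(outdir, "lmm.csv"),
                     row.names = FALSE)
    jsonlite::write_json(run_results_json(res),
                         file.path(outdir, "results.json"),
                         auto_unbox = TRUE, digits = 10)
  }
  structure(res, class = "cp_run")
}

run_results_json <- function(res) {
  list(
    seed = res$config$seed,
    fold_changes = stats::setNames(as.list(res$fold_changes$fold_change),
                                   as.character(res$fold_changes$organ)),
    fold_p = stats::setNames(as.list(res$fold_changes$p_value),
                             as.character(res$fold_changes$organ)),
    deficits = stats::setNames(as.list(res$organ_deficits$deficit),
                               res$organ_deficits$organ),
    lmm_load_slopes = stats::setNames(as.list(res$biometry_models$estimate),
                                      paste(res$biometry_models$organ,
                                            res$biometry_models$response,
                                            sep = ".")),
    mfa_inertia_dim12 = res$mfa$fit$eig$cum_pct[2],
    pooling_permitted = all(res$within_litter$pooling_permitted)
  )
}

#' @export
print.cp_run <- function(x, ...) {
  cat("<cp_run> seed", x$config$seed, "\n\nFold changes (exposed/control):\n")
  print(x$fold_changes[, c("organ", "fold_change", "p_value")])
  cat("\nDeficits vs placenta (exposed):\n")
  print(x$organ_deficits[, c("organ", "deficit", "p_value")])
  invisible(x)
}
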