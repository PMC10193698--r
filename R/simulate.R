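# Geometry grids (polar coordinates per tile size) are cached per session:
# they are deterministic so caching does not interact with the RNG.
.cpscan_cache <- new.env(parent = emptyenv())

polar_grid <- function(n) {
  key <- paste0("polar", n)
  g <- .cpscan_cache[[key]]
  if (is.null(g)) {
    u <- (seq_len(n) - (n + 1) / 2) / n
    ug <- matrix(u, n, n)
    vg <- matrix(u, n, n, byrow = TRUE)
    g <- list(r = sqrt(ug^2 + vg^2), theta = atan2(ug, vg))
    .cpscan_cache[[key]] <- g
  }
  g
}

# Smooth random field on an n x n grid: coarse Gaussian noise with one node
# per `scale_px` pixels, bilinearly interpolated. Mean ~0, SD ~1.
smooth_field <- function(n, scale_px) {
  m <- max(2L, ceiling(n / scale_px) + 1L)
  g <- matrix(stats::rnorm(m * m), m, m)
  # bilinear interpolation as two small matrix products
  pos <- (seq_len(n) - 0.5) / n * (m - 1) + 1
  lo <- pmin(floor(pos), m - 1)
  w <- pos - lo
  a <- matrix(0, n, m)
  a[cbind(seq_len(n), lo)] <- 1 - w
  a[cbind(seq_len(n), lo + 1)] <- w
  a %*% g %*% t(a)
}

#' Generate a synthetic tissue mask
#'
#' A smooth blob (circle with random angular modulation of its radius,
#' clipped to the tile) whose area is tuned by bisection to cover the
#' requested fraction of the tile within 1%.
#'
#' @param n Tile edge, pixels.
#' @param tissue_fraction Fraction of the tile covered by tissue, in (0, 1].
#' @return Logical `n x n` matrix.
#' @keywords internal
make_tissue_mask <- function(n, tissue_fraction = 0.85) {
  stopifnot(tissue_fraction > 0, tissue_fraction <= 1)
  if (tissue_fraction > 0.99) {
    return(matrix(TRUE, n, n))
  }
  g <- polar_grid(n)
  k <- sample(2:4, 1)
  phase <- stats::runif(1, 0, 2 * pi)
  amp <- stats::runif(1, 0.05, 0.15)
  # normalized radius: the blob is {q <= s}; picking s as the
  # tissue_fraction-quantile of q makes the covered area exact by definition
  q <- g$r / (1 + amp * cos(k * g$theta + phase))
  k_th <- ceiling(tissue_fraction * n * n)
  s <- sort.int(q, partial = k_th)[k_th]
  q <= s
}

# Additive Gaussian PSF stamp of one particle into a lambda image (in place
# semantics via return). Subpixel centre supported.
stamp_particles <- function(lam, centroids, amp, sigma) {
  if (length(amp) == 0) return(lam)
  n <- nrow(lam)
  r <- max(3L, ceiling(4 * sigma))
  for (i in seq_along(amp)) {
    cr <- centroids[i, 1]; cc <- centroids[i, 2]
    rows <- max(1L, floor(cr) - r):min(n, floor(cr) + r)
    cols <- max(1L, floor(cc) - r):min(n, floor(cc) + r)
    if (!length(rows) || !length(cols)) next
    kr <- exp(-((rows - cr)^2) / (2 * sigma^2))
    kc <- exp(-((cols - cc)^2) / (2 * sigma^2))
    lam[rows, cols] <- lam[rows, cols] + amp[i] * outer(kr, kc)
  }
  lam
}

# Sparse curvilinear collagen structures (narrow channel only), confined to
# the tissue mask. Each structure is a random quadratic curve stamped with a
# 3x3 softening kernel.
collagen_lambda <- function(n, mask, imaging) {
  lam <- matrix(0, n, n)
  area_mm2 <- sum(mask) * (imaging$pixel_size_um * 1e-3)^2
  n_curves <- stats::rpois(1, imaging$collagen_per_mm2 * area_mm2)
  if (n_curves == 0) return(lam)
  for (i in seq_len(n_curves)) {
    p <- matrix(stats::runif(6, 1, n), 3, 2)        # control points
    t <- seq(0, 1, length.out = max(16, round(n / 2)))
    b <- cbind((1 - t)^2, 2 * t * (1 - t), t^2) %*% p
    rr <- round(b[, 1]); cc <- round(b[, 2])
    keep <- rr >= 2 & rr <= n - 1 & cc >= 2 & cc <= n - 1
    rr <- rr[keep]; cc <- cc[keep]
    if (!length(rr)) next
    peak <- imaging$collagen_peak * exp(stats::rnorm(1, 0, 0.25))
    peak <- min(peak, 0.85 * imaging$saturation_level)
    taper <- peak * sin(pi * seq_along(rr) / (length(rr) + 1))
    for (dr in -1:1) for (dc in -1:1) {
      w <- if (dr == 0 && dc == 0) 1 else 0.35
      idx <- cbind(rr + dr, cc + dc)
      lam[idx] <- pmax(lam[idx], w * taper)
    }
  }
  lam * mask
}

# Detected counts: Poisson shot noise plus Gaussian read noise. Where the
# expected count is >= 12 the Poisson component is drawn from its
# moment-matched normal limit (folded with the read noise in quadrature);
# below that it is drawn exactly. Counts are quantised to integers and
# clipped to [0, saturation].
shot_read_noise <- function(lam, read_sd, sat, base_lambda = NULL) {
  nn <- length(lam)
  if (!is.null(base_lambda) && base_lambda < 12) {
    y <- stats::rpois(nn, base_lambda) + stats::rnorm(nn, 0, read_sd)
    bright <- which(lam > base_lambda + 1e-9)
    if (length(bright)) {
      lb <- lam[bright]
      y[bright] <- stats::rnorm(length(bright), lb, sqrt(lb + read_sd^2))
    }
  } else {
    y <- stats::rnorm(nn, lam, sqrt(lam + read_sd^2))
  }
  y <- round(y)
  y[y < 0] <- 0
  y[y > sat] <- sat
  dim(y) <- dim(lam)
  y
}

#' Render one synthetic two-channel tile scan
#'
#' Renders the broad autofluorescence channel (smooth textured tissue signal
#' restricted to the tissue region) and the narrow second-harmonic channel
#' (dark background with sparse curvilinear collagen structures), then adds
#' every particle to *both* channels as a point-spread blurred spot whose
#' peak exceeds the detector maximum, so particle cores clip at saturation in
#' both channels while collagen stays well below the broad-channel detection
#' regime. Shot and read noise are applied per pixel unless `noise = FALSE`.
#'
#' @param centroids Two-column matrix (row, col) of particle centres, possibly
#'   with zero rows. Must lie inside the tile.
#' @param imaging An [imaging_config()].
#' @param tissue_fraction Fraction of the tile covered by tissue; used only
#'   when `mask` is not supplied.
#' @param mask Optional logical tissue mask to render into.
#' @param noise Apply shot/read noise (default `TRUE`).
#' @param sample_id,region_id Identifiers carried into the result.
#' @return A [tile_scan()] whose `truth` attribute holds the true tissue
#'   mask and the centroid matrix.
#' @export
render_tile <- function(centroids, imaging = imaging_config(),
                        tissue_fraction = 0.85, mask = NULL, noise = TRUE,
                        sample_id = NA_character_, region_id = NA_integer_) {
  n <- imaging$tile_pixels
  if (n < 1) stop("zero-sized tile", call. = FALSE)
  centroids <- as.matrix(centroids)
  if (length(centroids) && ncol(centroids) != 2) {
    stop("centroids must be a two-column (row, col) matrix", call. = FALSE)
  }
  if (length(centroids) &&
      (any(centroids < 0.5) || any(centroids > n + 0.5))) {
    stop("centroids must lie inside the tile", call. = FALSE)
  }
  if (is.null(mask)) mask <- make_tissue_mask(n, tissue_fraction)

  texture <- pmax(1 + imaging$texture_amp *
                    smooth_field(n, imaging$texture_scale_px), 0.2)
  lam_broad <- imaging$dark_level + mask * (imaging$broad_background * texture)
  lam_narrow <- imaging$narrow_background + collagen_lambda(n, mask, imaging)

  n_part <- if (length(centroids)) nrow(centroids) else 0L
  if (n_part > 0) {
    amp <- imaging$particle_peak_factor * imaging$saturation_level *
      exp(stats::rnorm(n_part, 0, 0.2))
    lam_broad <- stamp_particles(lam_broad, centroids, amp, imaging$psf_sigma_px)
    lam_narrow <- stamp_particles(lam_narrow, centroids, amp, imaging$psf_sigma_px)
  }

  sat <- imaging$saturation_level
  if (noise) {
    broad <- shot_read_noise(lam_broad, imaging$read_noise_sd, sat)
    narrow <- shot_read_noise(lam_narrow, imaging$read_noise_sd, sat,
                              base_lambda = imaging$narrow_background)
  } else {
    broad <- matrix(pmin(lam_broad, sat), n, n)
    narrow <- matrix(pmin(lam_narrow, sat), n, n)
  }

  out <- tile_scan(narrow = narrow, broad = broad,
                   pixel_size_um = imaging$pixel_size_um,
                   section_thickness_um = imaging$section_thickness_um,
                   sample_id = sample_id, region_id = region_id)
  attr(out, "truth") <- list(mask = mask, centroids = centroids)
  out
}

#' Render a synthetic z-stack around embedded and surface particles
#'
#' Optical sectioning through the physical section: embedded particles get a
#' Gaussian axial profile (SD `axial_sigma_um`) centred at their depth, so
#' their signal peaks in an interior slice and spans several slices; surface
#' contaminants are planted with signal confined to the boundary slice
#' nearest their depth. A faint tissue background plus read noise fills the
#' remaining voxels.
#'
#' @param particles Data frame with columns `row`, `col`, `depth_um` and
#'   logical `surface`. Depths must lie within the section thickness.
#' @param imaging An [imaging_config()].
#' @param n_slices Number of optical slices (default `imaging$z_n_slices`).
#' @param noise Apply noise (default `TRUE`).
#' @return A `z_stack`: 3-D array with attributes `slice_spacing_um`,
#'   `pixel_size_um` and a `truth` ledger of planted depths.
#' @export
render_zstack <- function(particles, imaging = imaging_config(),
                          n_slices = imaging$z_n_slices, noise = TRUE) {
  if (n_slices < 3) stop("a z-stack needs at least 3 slices", call. = FALSE)
  particles <- as.data.frame(particles)
  if (nrow(particles) &&
      (any(particles$depth_um < 0) ||
       any(particles$depth_um > imaging$section_thickness_um))) {
    stop("particle depths must lie within the section thickness", call. = FALSE)
  }
  n <- min(imaging$tile_pixels, 128L)  # z-stacks are small fields of view
  dz <- imaging$z_slice_um
  z_of_slice <- (seq_len(n_slices) - 1) * dz
  axial_sigma <- 1.6 * dz
  sat <- imaging$saturation_level
  stack <- array(0, dim = c(n, n, n_slices))
  base <- imaging$broad_background / 4
  for (s in seq_len(n_slices)) {
    lam <- matrix(base, n, n)
    if (nrow(particles)) {
      for (i in seq_len(nrow(particles))) {
        p <- particles[i, ]
        if (isTRUE(p$surface)) {
          boundary <- if (p$depth_um <= imaging$section_thickness_um / 2) 1L
                      else n_slices
          ax <- as.numeric(s == boundary)
        } else {
          ax <- exp(-(z_of_slice[s] - p$depth_um)^2 / (2 * axial_sigma^2))
        }
        if (ax > 1e-4) {
          amp <- imaging$particle_peak_factor * sat * ax
          lam <- stamp_particles(lam, cbind(p$row, p$col), amp,
                                 imaging$psf_sigma_px)
        }
      }
    }
    stack[, , s] <- if (noise) {
      shot_read_noise(lam, imaging$read_noise_sd, sat)
    } else {
      matrix(pmin(lam, sat), n, n)
    }
  }
  structure(stack,
            slice_spacing_um = dz,
            pixel_size_um = imaging$pixel_size_um,
            truth = particles,
            class = "z_stack")
}

#' Simulate the ground truth of a full gestational exposure study
#'
#' Draws, without rendering any image, the true particle density of every
#' fetus-by-organ sample and the matched biometry of every fetus. Densities
#' follow the lognormal hierarchy of [organ_effects()]: organ-by-group mean
#' times a dam-level factor shared across all organs of a litter times an
#' independent fetus-by-organ factor, both mean-corrected. Biometry is drawn
#' around the configured weight medians, and the placenta/fetus weight ratio
#' responds to the fetus's true log10 placental load with the configured
#' slope, so mixed-model recovery is testable against a known truth.
#'
#' @param design A [study_design()].
#' @param effects An [organ_effects()].
#' @param imaging An [imaging_config()] (carried as metadata).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A `cp_sim` list: `study` (tidy fetus-by-organ table with
#'   `true_density` and biometry columns), `fetuses` (wide per-fetus biometry)
#'   and the three configuration objects.
#' @export
simulate_study <- function(design = study_design(),
                           effects = organ_effects(),
                           imaging = imaging_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  organs <- design$organs
  means <- organ_mean_density(effects, design)
  bio <- effects$biometry

  dams <- tidyr::expand_grid(
    group = factor(design$groups, levels = design$groups),
    dam_index = seq_len(design$n_dams_per_group)
  )
  dams$dam_id <- sprintf("%s%02d", as.character(dams$group), dams$dam_index)
  dams$dam_factor <- exp(stats::rnorm(nrow(dams), -effects$dam_sd_log^2 / 2,
                                      effects$dam_sd_log))
  dams$dam_ratio_b <- stats::rnorm(nrow(dams), 0, bio$ratio_dam_sd)
  dams$dam_ratio_slope_b <- stats::rnorm(nrow(dams), 0,
                                         bio$ratio_dam_slope_sd)

  fet <- tidyr::expand_grid(
    dams[, c("group", "dam_id", "dam_factor", "dam_ratio_b",
             "dam_ratio_slope_b")],
    fetus_index = seq_len(design$n_fetuses_per_dam)
  )
  fet$fetus_id <- sprintf("%s_f%d", fet$dam_id, fet$fetus_index)
  fet$sex <- factor(ifelse(stats::runif(nrow(fet)) < design$sex_ratio,
                           "M", "F"), levels = c("F", "M"))

  means$group <- factor(means$group, levels = design$groups)
  study <- tidyr::expand_grid(fet, organ = organs)
  study <- dplyr::left_join(study, means, by = c("organ", "group"))
  study$organ <- factor(study$organ, levels = organs)
  study$fetus_factor <- exp(stats::rnorm(nrow(study),
                                         -effects$fetus_sd_log^2 / 2,
                                         effects$fetus_sd_log))
  study$true_density <- study$mean_density * study$dam_factor *
    study$fetus_factor

  # ---- biometry (per fetus) -------------------------------------------------
  pl <- study[study$organ == "placenta", ]
  pl <- pl[match(fet$fetus_id, pl$fetus_id), ]
  sexadj <- ifelse(fet$sex == "M", bio$sex_effect_log / 2,
                   -bio$sex_effect_log / 2)
  fet$fetal_weight_g <- bio$fetal_weight_g *
    exp(sexadj + stats::rnorm(nrow(fet), 0, bio$weight_cv))
  centre <- log10(effects$placenta_control_density *
                    sqrt(effects$fold_change[["placenta"]]))
  fet$ratio_x10 <- pmax(
    bio$ratio_intercept +
      (bio$ratio_slope_per_decade + fet$dam_ratio_slope_b) *
        (log10(pl$true_density) - centre) +
      fet$dam_ratio_b +
      stats::rnorm(nrow(fet), 0, bio$ratio_resid_sd),
    0.3)
  fet$placenta_g <- fet$ratio_x10 * fet$fetal_weight_g / 10
  for (o in names(bio$organ_weight_g)) {
    fet[[paste0(o, "_g")]] <- bio$organ_weight_g[[o]] *
      exp(stats::rnorm(nrow(fet), 0, bio$weight_cv))
  }
  fet$gonad_g <- NA_real_

  organ_w <- tibble::tibble(
    fetus_id = rep(fet$fetus_id, length(organs)),
    organ = factor(rep(organs, each = nrow(fet)), levels = organs),
    organ_weight_g = c(fet$placenta_g, fet$heart_g, fet$kidney_g,
                       fet$liver_g, fet$lung_g, fet$gonad_g)
  )
  study <- dplyr::left_join(study, organ_w, by = c("fetus_id", "organ"))
  study <- dplyr::left_join(
    study,
    fet[, c("fetus_id", "fetal_weight_g")],
    by = "fetus_id"
  )
  study <- tibble::as_tibble(study[, c("dam_id", "group", "fetus_id", "sex",
                                       "organ", "true_density",
                                       "fetal_weight_g", "organ_weight_g")])
  fet_out <- tibble::as_tibble(
    fet[, c("dam_id", "group", "fetus_id", "sex", "fetal_weight_g",
            "placenta_g", "heart_g", "kidney_g", "liver_g", "lung_g",
            "gonad_g", "ratio_x10")])

  structure(
    list(study = study, fetuses = fet_out, design = design,
         effects = effects, imaging = imaging, seed = seed),
    class = "cp_sim"
  )
}
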