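# Block-mean downsample of a square matrix by integer factor f (n %% f == 0).
block_mean <- function(m, f) {
  if (f == 1) return(m)
  n <- nrow(m); k <- n / f
  m <- array(m, c(f, k, n))
  m <- colMeans(m)                       # k x n
  m <- array(t(m), c(f, k, k))
  t(colMeans(m))                         # k x k
}

# Separable box blur (radius r) via cumulative sums; cheap stand-in smoother
# applied twice to approximate a Gaussian.
box_blur <- function(m, r) {
  n <- nrow(m); w <- 2 * r + 1
  pad <- function(x) rbind(matrix(x[1, ], r, ncol(x), byrow = TRUE), x,
                           matrix(x[nrow(x), ], r, ncol(x), byrow = TRUE))
  sweep1 <- function(x) {
    cs <- apply(pad(x), 2, cumsum)
    (cs[w:(n + w - 1), , drop = FALSE] -
       rbind(0, cs[1:(n - 1), , drop = FALSE])) / w
  }
  t(sweep1(t(sweep1(m))))
}

#' Segment the tissue region of a tile scan
#'
#' Automated stand-in for the manual tissue-area delineation step: the broad
#' autofluorescence channel is block-downsampled (processing edge at most 128
#' px), smoothed, thresholded globally (Otsu), morphologically closed, holes
#' are filled, and small objects removed; the mask is then upsampled back to
#' the tile grid. A contrast guard returns a zero-area mask when the tile
#' shows no tissue (foreground less than twice the background level).
#'
#' When Otsu finds no bimodal separation (foreground/background contrast
#' below 2) the tile is either all tissue or all empty; the two are told
#' apart by comparing the mean level against `min_tissue_level`, a floor
#' safely above detector dark level plus read noise.
#'
#' @param tile A [tile_scan()].
#' @param min_tissue_level Minimum mean intensity (counts) for a
#'   non-bimodal tile to count as tissue-everywhere.
#' @return A `tissue_mask`: logical matrix with attributes `pixel_size_um`
#'   and `area_mm2`.
#' @export
segment_tissue <- function(tile, min_tissue_level = 20) {
  stopifnot(inherits(tile, "tile_scan"))
  br <- tile$broad
  n <- nrow(br)
  f <- 1L
  for (cand in c(8L, 4L, 2L)) {
    if (n %% cand == 0 && n / cand >= 48 && n / cand <= 192) { f <- cand; break }
  }
  if (f == 1L && n > 192) f <- max(1L, n %/% 128L)
  ds <- if (n %% f == 0) block_mean(br, f) else { f <- 1L; br }
  ds <- box_blur(ds, 1L)

  mx <- max(ds)
  empty <- function() {
    mask <- matrix(FALSE, n, n)
    attr(mask, "pixel_size_um") <- tile$pixel_size_um
    attr(mask, "area_mm2") <- 0
    class(mask) <- c("tissue_mask", class(mask))
    mask
  }
  full <- function() {
    mask <- matrix(TRUE, n, n)
    attr(mask, "pixel_size_um") <- tile$pixel_size_um
    attr(mask, "area_mm2") <- mask_area(mask, tile$pixel_size_um)
    class(mask) <- c("tissue_mask", class(mask))
    mask
  }
  if (mx <= 0) return(empty())
  # threshold on the log intensity: saturating particle spots inside the
  # tissue would otherwise dominate the between-class variance and make the
  # global threshold separate particles from tissue instead of tissue from
  # background; the log compresses that tail so the dark/tissue split wins
  lg <- log1p(ds)
  thr <- EBImage::otsu(EBImage::Image(lg / max(lg)), range = c(0, 1)) * max(lg)
  fg <- lg > thr
  no_contrast <- !any(fg) || all(fg) ||
    mean(ds[fg]) < 2 * mean(ds[!fg]) + 1e-12
  if (no_contrast) {
    return(if (mean(ds) >= min_tissue_level) full() else empty())
  }

  img <- EBImage::Image(fg * 1)
  img <- EBImage::closing(img, EBImage::makeBrush(5, "disc"))
  img <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(img)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= 0.01 * length(lab)])
  fg <- matrix(as.array(lab) %in% keep, nrow(lab), ncol(lab))
  if (!any(fg)) return(empty())

  mask <- if (f > 1) {
    matrix(as.logical(kronecker(fg * 1, matrix(1, f, f))), n, n)
  } else {
    fg
  }
  attr(mask, "pixel_size_um") <- tile$pixel_size_um
  attr(mask, "area_mm2") <- mask_area(mask, tile$pixel_size_um)
  class(mask) <- c("tissue_mask", class(mask))
  mask
}

#' Volumetric particle load
#'
#' Converts an areal particle count into a volumetric load using the tissue
#' area of the imaged region and the physical section thickness:
#' `load = n / (area_mm2 * thickness_um * 1e-3)` particles per mm^3.
#'
#' @param n_particles Particle count (>= 0).
#' @param area_mm2 Tissue area of the region, mm^2 (> 0).
#' @param thickness_um Section thickness, micrometres (default 7).
#' @return Load in particles per mm^3.
#' @export
load_per_mm3 <- function(n_particles, area_mm2, thickness_um = 7) {
  stopifnot(all(n_particles >= 0), thickness_um > 0)
  if (any(area_mm2 <= 0)) {
    stop("tissue area must be positive to normalise a load", call. = FALSE)
  }
  n_particles / (area_mm2 * thickness_um * 1e-3)
}

#' Aggregate region loads into a per-sample load
#'
#' The sample load is the unweighted mean of the per-region loads (the
#' `"mean"` method) or the pooled count divided by the pooled volume (the
#' `"pooled"` method, weighting regions by tissue area). Regions with zero
#' tissue area are excluded with a warning, and samples with fewer than
#' `n_min` usable regions are flagged as under-sampled.
#'
#' @param loads Per-region loads (particles/mm^3). For `method = "pooled"`,
#'   supply `counts` and `areas_mm2` instead.
#' @param n_min Minimum regions expected per sample (default 5).
#' @param method `"mean"` (default) or `"pooled"`.
#' @param counts,areas_mm2,thickness_um Region counts/areas for the pooled
#'   method.
#' @return List with `sample_load`, `n_regions`, `flagged`, `region_loads`.
#' @export
aggregate_sample <- function(loads = NULL, n_min = 5,
                             method = c("mean", "pooled"),
                             counts = NULL, areas_mm2 = NULL,
                             thickness_um = 7) {
  method <- match.arg(method)
  if (method == "pooled") {
    stopifnot(!is.null(counts), !is.null(areas_mm2),
              length(counts) == length(areas_mm2))
    ok <- areas_mm2 > 0
    if (any(!ok)) warning(sum(!ok), " region(s) with zero tissue area excluded",
                          call. = FALSE)
    counts <- counts[ok]; areas_mm2 <- areas_mm2[ok]
    if (!length(counts)) stop("no valid regions", call. = FALSE)
    loads_used <- load_per_mm3(counts, areas_mm2, thickness_um)
    sample_load <- sum(counts) / (sum(areas_mm2) * thickness_um * 1e-3)
  } else {
    ok <- is.finite(loads)
    if (any(!ok)) warning(sum(!ok), " invalid region load(s) excluded",
                          call. = FALSE)
    loads_used <- loads[ok]
    if (!length(loads_used)) stop("no valid regions", call. = FALSE)
    sample_load <- mean(loads_used)
  }
  list(sample_load = sample_load,
       n_regions = length(loads_used),
       flagged = length(loads_used) < n_min,
       region_loads = loads_used)
}

#' Pool a fetus-level study table per litter
#'
#' Averages the fetus-level loads (and any biometry columns present) within
#' each dam and organ, so that the dam (litter) becomes the statistical unit
#' of all downstream group comparisons. Pooling an already litter-level
#' table is the identity.
#'
#' @param study Tidy table with columns `dam_id`, `group`, `organ`,
#'   `cp_load` and optionally numeric biometry columns.
#' @return Litter-level tibble, one row per dam and organ, with `n_fetuses`.
#' @export
pool_by_dam <- function(study) {
  stopifnot(all(c("dam_id", "group", "organ", "cp_load") %in% names(study)))
  num_cols <- intersect(
    names(study)[vapply(study, is.numeric, logical(1))],
    c("cp_load", "true_density", "fetal_weight_g", "organ_weight_g")
  )
  study |>
    dplyr::group_by(.data$dam_id, .data$group, .data$organ) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(num_cols), ~ mean(.x, na.rm = TRUE)),
      n_fetuses = dplyr::n(),
      .groups = "drop"
    )
}

#' Derive biometry ratio columns
#'
#' Adds the derived fetoplacental ratios on their conventional display
#' scales: placental efficiency (fetal / placental weight), placenta/fetus
#' weight ratio x10, heart and kidney somatic ratios x10^3, liver and lung
#' ratios x10^2. Placental efficiency times the unscaled placenta/fetus
#' ratio is exactly 1 per fetus.
#'
#' @param fetuses Wide per-fetus tibble with `fetal_weight_g`, `placenta_g`,
#'   `heart_g`, `kidney_g`, `liver_g`, `lung_g`.
#' @return The input with ratio columns appended.
#' @export
derive_biometry <- function(fetuses) {
  need <- c("fetal_weight_g", "placenta_g")
  stopifnot(all(need %in% names(fetuses)))
  if (any(fetuses$fetal_weight_g <= 0, na.rm = TRUE) ||
      any(fetuses$placenta_g <= 0, na.rm = TRUE)) {
    stop("weights must be positive", call. = FALSE)
  }
  out <- fetuses
  out$placental_efficiency <- out$fetal_weight_g / out$placenta_g
  out$placenta_fetus_ratio_x10 <- 10 * out$placenta_g / out$fetal_weight_g
  if ("heart_g" %in% names(out)) {
    out$heart_fetus_ratio_x1e3 <- 1e3 * out$heart_g / out$fetal_weight_g
  }
  if ("kidney_g" %in% names(out)) {
    out$kidney_fetus_ratio_x1e3 <- 1e3 * out$kidney_g / out$fetal_weight_g
  }
  if ("liver_g" %in% names(out)) {
    out$liver_fetus_ratio_x1e2 <- 1e2 * out$liver_g / out$fetal_weight_g
  }
  if ("lung_g" %in% names(out)) {
    out$lung_fetus_ratio_x1e2 <- 1e2 * out$lung_g / out$fetal_weight_g
  }
  out
}
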