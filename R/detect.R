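#' Fractional-of-maximum channel threshold
#'
#' Marks every pixel whose intensity is at least `fraction` times the
#' channel's own maximum. The tile scan is the acquisition unit, so the
#' maximum is taken per channel per tile; all pixels tied at the maximum pass
#' by construction (`>=` comparison). A constant-zero channel yields an empty
#' mask with a warning, since no particle is callable without signal.
#'
#' @param channel Numeric intensity matrix.
#' @param fraction Fraction of the channel maximum, in (0, 1].
#' @return Logical mask with attribute `threshold` (the absolute cut) and
#'   `channel_max`.
#' @export
channel_threshold <- function(channel, fraction) {
  stopifnot(is.numeric(fraction), fraction > 0, fraction <= 1,
            length(channel) > 0)
  mx <- max(channel)
  if (mx <= 0) {
    warning("constant-zero channel: no particles callable", call. = FALSE)
    mask <- matrix(FALSE, nrow(channel), ncol(channel))
    attr(mask, "threshold") <- NA_real_
    attr(mask, "channel_max") <- mx
    return(mask)
  }
  thr <- fraction * mx
  mask <- channel >= thr
  attr(mask, "threshold") <- thr
  attr(mask, "channel_max") <- mx
  mask
}

# Connected-component labelling of a sparse pixel set, written directly on
# the (row, col) list so cost scales with the number of foreground pixels,
# not the image. Union-find with path compression; 4- or 8-connectivity.
label_sparse <- function(rows, cols, nrow_img, connectivity = 8) {
  np <- length(rows)
  if (np == 0) return(integer(0))
  ids <- (cols - 1) * nrow_img + rows       # linear pixel ids
  parent <- seq_len(np)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- if (connectivity == 8) {
    c(-1, nrow_img - 1, nrow_img, nrow_img + 1)
  } else {
    c(-1, nrow_img)
  }
  # guard against column wrap-around for row-offset neighbours
  for (off in offsets) {
    nb <- match(ids + off, ids)
    ok <- which(!is.na(nb))
    if (off %in% c(-1, nrow_img - 1)) ok <- ok[rows[ok] > 1]
    if (off == nrow_img + 1) ok <- ok[rows[ok] < nrow_img]
    for (i in ok) {
      ra <- find(i); rb <- find(nb[i])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(np), find, integer(1))
  match(roots, unique(roots))
}

#' Call carbon particles on a two-channel tile scan
#'
#' The particle caller: both channels are thresholded at their configured
#' fraction of the per-tile maximum, the two masks are intersected (a genuine
#' particle emits across the whole visible spectrum, so it must exceed both
#' thresholds simultaneously, unlike collagen or autofluorescence), and each
#' connected component of the intersection with at least `min_component_px`
#' pixels becomes one particle. Centroids are means of the component pixel
#' coordinates.
#'
#' @param tile A [tile_scan()].
#' @param params A [detection_params()].
#' @return A `particle_calls` object: list with `particles` (tibble:
#'   `particle`, `row`, `col`, `n_px`, list-column `pixels`), `n`,
#'   `thresholds`, `channel_max`, `params` and the tile identifiers.
#' @export
call_particles <- function(tile, params = detection_params()) {
  stopifnot(inherits(tile, "tile_scan"))
  if (!all(dim(tile$narrow) == dim(tile$broad))) {
    stop("channel shape mismatch", call. = FALSE)
  }
  m_narrow <- suppressWarnings(
    channel_threshold(tile$narrow, params$narrow_fraction))
  m_broad <- suppressWarnings(
    channel_threshold(tile$broad, params$broad_fraction))
  inter <- m_narrow & m_broad

  px <- which(inter)
  nr <- nrow(inter)
  rows <- ((px - 1) %% nr) + 1
  cols <- ((px - 1) %/% nr) + 1
  lab <- label_sparse(rows, cols, nr, params$connectivity)

  if (length(lab)) {
    comp <- split(seq_along(lab), lab)
    sizes <- lengths(comp)
    comp <- comp[sizes >= params$min_component_px]
    particles <- tibble::tibble(
      particle = seq_along(comp),
      row = vapply(comp, function(i) mean(rows[i]), numeric(1)),
      col = vapply(comp, function(i) mean(cols[i]), numeric(1)),
      n_px = lengths(comp),
      pixels = lapply(comp, function(i) cbind(row = rows[i], col = cols[i]))
    )
  } else {
    particles <- tibble::tibble(
      particle = integer(0), row = numeric(0), col = numeric(0),
      n_px = integer(0), pixels = list()
    )
  }

  structure(
    list(
      particles = particles,
      n = nrow(particles),
      thresholds = c(narrow = attr(m_narrow, "threshold"),
                     broad = attr(m_broad, "threshold")),
      channel_max = c(narrow = attr(m_narrow, "channel_max"),
                      broad = attr(m_broad, "channel_max")),
      params = params,
      sample_id = tile$sample_id,
      region_id = tile$region_id
    ),
    class = "particle_calls"
  )
}

#' @export
print.particle_calls <- function(x, ...) {
  cat(sprintf("<particle_calls> %d particle(s); thresholds narrow %.4g, broad %.4g\n",
              x$n, x$thresholds[["narrow"]], x$thresholds[["broad"]]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @exportS3Method generics::tidy
tidy.particle_calls <- function(x, ...) {
  out <- x$particles[, c("particle", "row", "col", "n_px")]
  out$sample_id <- x$sample_id
  out$region_id <- x$region_id
  out
}

#' Classify a called particle as tissue-embedded or surface contamination
#'
#' Inspects the axial intensity profile of a small window around the call in
#' an optical z-stack. A particle is `"embedded"` when its signal maximum
#' falls in an interior slice and the signal spans at least two slices;
#' `"surface"` when the signal is confined to the first or last slice; and
#' `"indeterminate"` when no clear signal rises above the stack background
#' (less than `min_signal` counts over baseline).
#'
#' @param z A `z_stack`.
#' @param centroid Length-2 numeric (row, col).
#' @param window Half-width of the inspection window, pixels.
#' @param min_signal Minimum peak-over-baseline (counts) to call signal.
#' @return One of `"embedded"`, `"surface"`, `"indeterminate"`, with the
#'   per-slice profile attached as attribute `profile`.
#' @export
verify_embedment <- function(z, centroid, window = 4, min_signal = 20) {
  d <- dim(z)
  r <- round(centroid[1]); c <- round(centroid[2])
  if (r < 1 || c < 1 || r > d[1] || c > d[2]) {
    stop("centroid outside stack", call. = FALSE)
  }
  rows <- max(1, r - window):min(d[1], r + window)
  cols <- max(1, c - window):min(d[2], c + window)
  profile <- apply(z[rows, cols, , drop = FALSE], 3, max)
  baseline <- stats::median(profile)
  peak <- max(profile)
  verdict <- if (peak - baseline < min_signal) {
    "indeterminate"
  } else {
    signal <- which(profile > baseline + 0.25 * (peak - baseline))
    top <- which.max(profile)
    boundary <- c(1L, d[3])
    if (!(top %in% boundary) && length(signal) >= 2) {
      "embedded"
    } else if (all(signal %in% boundary[1]) || all(signal %in% boundary[2])) {
      "surface"
    } else {
      "indeterminate"
    }
  }
  attr(verdict, "profile") <- profile
  verdict
}
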