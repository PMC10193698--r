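# Population-variance standardization (1/n), the classical factorial
# convention: with uniform individual weights 1/n the total inertia of each
# standardized column is exactly 1.
standardize_pop <- function(x) {
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sd_pop < 1e-12)) {
    stop("constant variable(s): ",
         paste(colnames(x)[sd_pop < 1e-12], collapse = ", "), call. = FALSE)
  }
  sweep(sweep(x, 2, mu), 2, sd_pop, "/")
}

#' Multiple factor analysis (group-weighted PCA)
#'
#' From-scratch multiple factor analysis of a table of individuals described
#' by quantitative variables organised into groups. Each column is centred
#' and scaled to unit population variance; each group's columns are then
#' weighted by `1/sqrt(lambda1)` of that group's own standardized PCA, so
#' that no single group can contribute more than one unit of inertia to the
#' first global dimension; a global PCA (SVD with uniform individual weights
#' 1/n) of the weighted matrix yields eigenvalues, individual coordinates
#' and variable-dimension correlations. Dimension signs are fixed by forcing
#' the variable with the largest absolute correlation positive, so runs are
#' reproducible.
#'
#' @param data Data frame or matrix of quantitative variables; rows with
#'   missing values are dropped listwise (count reported in the result).
#' @param groups Named list mapping group names to column names, or a vector
#'   assigning a group label to every column. Every variable must belong to
#'   exactly one group.
#' @param n_dims Number of dimensions to retain (default `min(5, rank)`).
#' @return A `cp_mfa` object: `eig` (eigenvalue table), `ind` (individual
#'   coordinates), `var_cor` (variable-dimension correlations),
#'   `group_weights`, `row_index` (rows of `data` used), `n_dropped`.
#' @export
mfa <- function(data, groups, n_dims = 5) {
  x_all <- as.data.frame(data)
  if (is.list(groups)) {
    cols <- unlist(groups, use.names = FALSE)
    grp <- rep(names(groups), lengths(groups))
  } else {
    cols <- names(groups)
    if (is.null(cols)) cols <- colnames(x_all)
    grp <- as.character(groups)
  }
  if (anyDuplicated(cols)) {
    stop("every variable must belong to exactly one group", call. = FALSE)
  }
  missing_cols <- setdiff(cols, names(x_all))
  if (length(missing_cols)) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(x_all[, cols, drop = FALSE])
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("at least 3 complete individuals required", call. = FALSE)

  z <- standardize_pop(x)
  lambda1 <- vapply(unique(grp), function(g) {
    zg <- z[, grp == g, drop = FALSE]
    (svd(zg / sqrt(n), nu = 0, nv = 0)$d[1])^2
  }, numeric(1))
  w <- 1 / sqrt(lambda1[grp])
  zw <- sweep(z, 2, w, "*")

  s <- svd(zw / sqrt(n))
  eigval <- s$d^2
  rank <- sum(s$d > 1e-10 * s$d[1])
  n_dims <- min(n_dims, rank)
  if (n_dims < 1) stop("degenerate input: rank zero", call. = FALSE)

  # individual coordinates: population variance of dimension d equals
  # lambda_d
  coords <- sqrt(n) * s$u[, seq_len(n_dims), drop = FALSE] %*%
    diag(s$d[seq_len(n_dims)], n_dims)
  # correlations of (unweighted, standardized) variables with dimensions
  var_cor <- stats::cor(z, coords)

  # deterministic sign convention
  for (d in seq_len(n_dims)) {
    iv <- which.max(abs(var_cor[, d]))
    if (var_cor[iv, d] < 0) {
      coords[, d] <- -coords[, d]
      var_cor[, d] <- -var_cor[, d]
    }
  }
  colnames(coords) <- paste0("dim", seq_len(n_dims))
  colnames(var_cor) <- paste0("dim", seq_len(n_dims))

  eig <- tibble::tibble(
    dim = seq_along(eigval),
    eigenvalue = eigval,
    pct_inertia = 100 * eigval / sum(eigval),
    cum_pct = cumsum(100 * eigval / sum(eigval))
  )
  ind <- tibble::as_tibble(as.data.frame(coords))
  ind$row <- which(keep)
  var_tbl <- tibble::as_tibble(as.data.frame(var_cor))
  var_tbl$variable <- cols
  var_tbl$group <- grp
  var_tbl <- var_tbl[, c("variable", "group",
                         paste0("dim", seq_len(n_dims)))]

  structure(
    list(eig = eig, ind = ind, var_cor = var_tbl,
         group_weights = 1 / lambda1, lambda1 = lambda1,
         n = n, n_dims = n_dims, n_dropped = sum(!keep),
         row_index = which(keep), columns = cols, group_of = grp),
    class = "cp_mfa"
  )
}

#' @export
print.cp_mfa <- function(x, ...) {
  cat(sprintf("<cp_mfa> %d individuals, %d variables in %d group(s); dim 1-2 carry %.1f%% of inertia\n",
              x$n, length(x$columns), length(unique(x$group_of)),
              x$eig$cum_pct[min(2, nrow(x$eig))]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cp_mfa <- function(x, ...) x$eig

#' @exportS3Method generics::glance
glance.cp_mfa <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_variables = length(x$columns),
    n_groups = length(unique(x$group_of)),
    n_dropped = x$n_dropped,
    inertia_dim12 = x$eig$cum_pct[min(2, nrow(x$eig))]
  )
}

#' Supplementary category statistics on the factor map
#'
#' Projects a qualitative factor (exposure group, exposure-by-sex, ...) onto
#' a fitted MFA as supplementary information: each level's coordinate is the
#' barycentre of its individuals, its `v.test` on dimension d is the
#' barycentre standardized by the exact variance of a mean of `n_k`
#' individuals drawn without replacement
#' (`sqrt(lambda_d / n_k * (n - n_k) / (n - 1))`), and its `cos2` is the
#' share of the barycentre's squared distance to the origin carried by that
#' dimension. `|v.test| > 1.96` conventionally flags significant separation.
#'
#' @param x A `cp_mfa`.
#' @param factor_values Factor (length = rows of the original data, or of
#'   the rows used) assigning each individual a level.
#' @return Tibble per level and dimension: `coord`, `v_test`, `cos2`,
#'   `significant`.
#' @export
supplementary_categories <- function(x, factor_values) {
  f <- align_factor(x, factor_values)
  n <- x$n
  lev <- levels(f)
  counts <- table(f)
  if (any(counts == 0) || any(counts == n)) {
    stop("every level needs 1 <= n_k < n individuals (v.test undefined otherwise)",
         call. = FALSE)
  }
  dims <- seq_len(x$n_dims)
  coords <- as.matrix(x$ind[, paste0("dim", dims)])
  purrr::map_dfr(lev, function(l) {
    idx <- which(f == l)
    nk <- length(idx)
    bary <- colMeans(coords[idx, , drop = FALSE])
    sd_bary <- sqrt(x$eig$eigenvalue[dims] / nk * (n - nk) / (n - 1))
    v <- bary / sd_bary
    tibble::tibble(
      level = l, dim = dims, n_k = nk, coord = unname(bary),
      v_test = unname(v),
      cos2 = unname(bary^2 / sum(bary^2)),
      significant = abs(v) > 1.96
    )
  })
}

align_factor <- function(x, factor_values) {
  f <- factor(factor_values)
  if (length(f) == x$n) return(droplevels(f))
  if (length(f) >= max(x$row_index)) return(droplevels(f[x$row_index]))
  stop("factor length does not match the individuals", call. = FALSE)
}

#' Share of a dimension's variance explained by a qualitative factor
#'
#' One-way analysis of variance of the individuals' coordinates on each
#' dimension against the factor: the R-squared and its F-test p-value. For a
#' two-level factor the R-squared equals the squared point-biserial
#' correlation.
#'
#' @param x A `cp_mfa`.
#' @param factor_values Qualitative factor, as in
#'   [supplementary_categories()].
#' @param dims Dimensions to describe (default all retained).
#' @return Tibble per dimension: `r_squared`, `p_value`.
#' @export
dimension_description <- function(x, factor_values, dims = seq_len(x$n_dims)) {
  f <- align_factor(x, factor_values)
  if (nlevels(f) < 2) stop("factor needs at least two levels", call. = FALSE)
  purrr::map_dfr(dims, function(d) {
    y <- x$ind[[paste0("dim", d)]]
    fit <- stats::lm(y ~ f)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    tibble::tibble(
      dim = d,
      r_squared = sm$r.squared,
      p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    )
  })
}

#' 95% confidence ellipse of a category barycentre
#'
#' Ellipse of the *mean* of a level's individuals on two dimensions: centred
#' on the barycentre, shaped by the sample covariance of the level's
#' coordinates divided by `n_k`, with radius scaled by the chi-squared(2)
#' quantile at the requested coverage. Shrinks as `1/sqrt(n_k)`.
#'
#' @param x A `cp_mfa`.
#' @param factor_values Qualitative factor.
#' @param level Level to compute the ellipse for (default: all levels).
#' @param coverage Coverage probability (default 0.95); 0 degenerates to the
#'   barycentre point.
#' @param dims Two dimensions (default 1:2).
#' @param n_points Points on the returned ellipse path.
#' @return Tibble of path points (`level`, `x`, `y`) with the per-level
#'   parameters in attribute `parameters`.
#' @export
confidence_ellipse <- function(x, factor_values, level = NULL,
                               coverage = 0.95, dims = c(1, 2),
                               n_points = 120) {
  stopifnot(length(dims) == 2, coverage >= 0, coverage < 1)
  f <- align_factor(x, factor_values)
  lev <- if (is.null(level)) levels(f) else level
  coords <- as.matrix(x$ind[, paste0("dim", dims)])
  r2 <- if (coverage == 0) 0 else stats::qchisq(coverage, df = 2)
  params <- list()
  paths <- purrr::map_dfr(lev, function(l) {
    idx <- which(f == l)
    if (length(idx) < 3) {
      stop("level '", l, "' needs n_k >= 3 for an ellipse", call. = FALSE)
    }
    cc <- coords[idx, , drop = FALSE]
    centre <- colMeans(cc)
    sigma <- stats::cov(cc) / length(idx)
    ev <- eigen(sigma, symmetric = TRUE)
    if (ev$values[2] < 1e-14 * max(ev$values[1], 1e-300)) {
      stop("degenerate covariance for level '", l,
           "' (collinear coordinates)", call. = FALSE)
    }
    params[[l]] <<- list(centre = centre, sigma = sigma,
                         semi_axes = sqrt(r2 * ev$values),
                         angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]))
    t <- seq(0, 2 * pi, length.out = n_points)
    circ <- rbind(cos(t), sin(t))
    pts <- t(centre + ev$vectors %*% diag(sqrt(pmax(r2 * ev$values, 0))) %*% circ)
    tibble::tibble(level = l, x = pts[, 1], y = pts[, 2])
  })
  attr(paths, "parameters") <- params
  paths
}

#' Variable factor map coordinates
#'
#' Correlation of every active variable (standardized, unweighted) with the
#' first two dimensions, plus the representation quality (sum of squared
#' correlations over the plotted dimensions). All points lie inside the
#' unit correlation circle.
#'
#' @param x A `cp_mfa`.
#' @param dims Two dimensions (default 1:2).
#' @return Tibble per variable: `corr_dim1`, `corr_dim2`, `quality`.
#' @export
variable_factor_map <- function(x, dims = c(1, 2)) {
  stopifnot(length(dims) == 2)
  v <- x$var_cor
  tibble::tibble(
    variable = v$variable,
    group = v$group,
    corr_dim1 = v[[paste0("dim", dims[1])]],
    corr_dim2 = v[[paste0("dim", dims[2])]],
    quality = v[[paste0("dim", dims[1])]]^2 + v[[paste0("dim", dims[2])]]^2
  )
}

#' Assemble the MFA input table of a study
#'
#' Builds the wide individuals-by-variables table: one row per fetus; the
#' log10 particle loads of the six compartments as the load group, the organ
#' weights as the weight group, and the derived weight ratios as the ratio
#' group. Exposure (and optionally sex) are returned alongside as
#' supplementary factors.
#'
#' @param study Fetus-level study table with `cp_load`.
#' @param fetuses Wide biometry from [derive_biometry()].
#' @return List: `data` (wide tibble), `groups` (named list), `exposure`,
#'   `exposure_sex` factors aligned to the rows.
#' @export
study_mfa_input <- function(study, fetuses) {
  loads <- study[, c("fetus_id", "organ", "cp_load")]
  loads$cp_load <- log10(replace_zero_loads(loads$cp_load))
  wide <- tidyr::pivot_wider(loads, names_from = "organ",
                             values_from = "cp_load",
                             names_glue = "load_{organ}")
  tab <- dplyr::left_join(fetuses, wide, by = "fetus_id")
  groups <- list(
    cp_load = paste0("load_", cp_organs()),
    organ_weight = c("fetal_weight_g", "placenta_g", "heart_g", "kidney_g",
                     "liver_g", "lung_g"),
    weight_ratio = c("placental_efficiency", "placenta_fetus_ratio_x10",
                     "heart_fetus_ratio_x1e3", "kidney_fetus_ratio_x1e3",
                     "liver_fetus_ratio_x1e2", "lung_fetus_ratio_x1e2")
  )
  groups <- lapply(groups, intersect, y = names(tab))
  list(
    data = tab,
    groups = groups,
    exposure = factor(tab$group),
    exposure_sex = factor(paste(tab$group, tab$sex, sep = "_"))
  )
}
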