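new_test_result <- function(statistic, p_value, method, exact, n) {
  tibble::tibble(
    statistic = statistic,
    p_value = p_value,
    method = method,
    exact = exact,
    n = list(n)
  )
}

#' Median (Q1; Q3) summary
#'
#' The summary convention of the study: median with first and third
#' quartiles, computed with the linear-interpolation quartile convention
#' (type 7) — the display depends on the convention, so it is fixed and
#' documented here.
#'
#' @param values Numeric vector (at least one value).
#' @return Tibble with `median`, `q1`, `q3`, `n` and a formatted `label`.
#' @export
quartile_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    median = q[2], q1 = q[1], q3 = q[3], n = length(values),
    label = sprintf("%.3g (%.3g; %.3g)", q[2], q[1], q[3])
  )
}

# Mann-Whitney U from midranks: U of sample x against y.
u_statistic <- function(rx, n, m) sum(rx) - n * (n + 1) / 2

#' Exact two-sided Mann-Whitney test
#'
#' Rank-sum comparison of two independent groups with the two-sided p-value
#' obtained by full enumeration of all `choose(n + m, n)` group labelings of
#' the observed (mid-)ranks whenever that number is at most `max_enumerate`
#' (the 7-vs-7 litter comparison needs only 3432), falling back to the
#' normal approximation with tie correction otherwise. Ties take midranks;
#' the two-sided p is the probability, under random labeling, of a U at
#' least as far from its null mean `nm/2` as observed — the exact analogue
#' of the usual symmetric two-sided rule.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param max_enumerate Enumeration budget on `choose(n + m, n)`.
#' @return One-row tibble: `statistic` (U of `x`), `p_value`, `method`,
#'   `exact`, `n`.
#' @export
mann_whitney_exact <- function(x, y, max_enumerate = 1e6) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  stopifnot(n >= 1, m >= 1)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  centre <- n * m / 2
  if (choose(n + m, n) <= max_enumerate) {
    combs <- utils::combn(n + m, n)
    rs <- colSums(matrix(r[combs], nrow = n))
    u_all <- rs - n * (n + 1) / 2
    p <- mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
    new_test_result(u_obs, p, "Mann-Whitney (exact enumeration)", TRUE,
                    c(n = n, m = m))
  } else {
    ties <- table(r)
    sigma2 <- n * m / 12 *
      ((n + m + 1) - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    z <- (u_obs - centre) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    new_test_result(u_obs, p, "Mann-Whitney (normal approximation)", FALSE,
                    c(n = n, m = m))
  }
}

#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Paired comparison used for within-fetus organ contrasts. Zero differences
#' are dropped (the standard convention), the absolute differences are
#' midranked, and for up to `max_n` informative pairs the two-sided p-value
#' is computed by enumerating all `2^n` sign patterns; beyond that a normal
#' approximation with tie correction is used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param max_n Enumeration limit on the number of non-zero differences.
#' @return One-row tibble as in [mann_whitney_exact()]; `statistic` is the
#'   positive-rank sum W+.
#' @export
wilcoxon_signed_rank_exact <- function(x, y, max_n = 20) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  centre <- sum(r) / 2
  if (n <= max_n) {
    signs <- matrix(as.logical(intToBits(seq_len(2^n) - 1L)),
                    nrow = 32)[seq_len(n), , drop = FALSE]
    w_all <- colSums(r * signs)
    p <- mean(abs(w_all - centre) >= abs(w_obs - centre) - 1e-9)
    new_test_result(w_obs, p, "Wilcoxon signed-rank (exact enumeration)",
                    TRUE, c(n = n))
  } else {
    sigma2 <- sum(r^2) / 4
    z <- (w_obs - centre) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    new_test_result(w_obs, p, "Wilcoxon signed-rank (normal approximation)",
                    FALSE, c(n = n))
  }
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Exact Spearman rank correlation
#'
#' Spearman's rho from midranks with a two-sided p-value by full enumeration
#' of all `n!` rank permutations for `n <= max_exact_n` (5040 permutations
#' at the study's n = 7), otherwise the t-distribution approximation.
#' Constant input has undefined rho and is flagged.
#'
#' @param x,y Numeric vectors, `n >= 3`.
#' @param max_exact_n Largest n for exact enumeration.
#' @return List with `rho` and `test` (a one-row result tibble).
#' @export
spearman_exact <- function(x, y, max_exact_n = 8) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  stopifnot(n >= 3)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(rho = NA_real_,
                test = new_test_result(NA_real_, NA_real_,
                                       "Spearman (undefined: constant input)",
                                       FALSE, c(n = n))))
  }
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(a, b) {
    stats::cor(a, b)
  }
  rho <- rho_of(rx, ry)
  if (n <= max_exact_n) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) rho_of(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
    list(rho = rho,
         test = new_test_result(rho, p, "Spearman (exact permutation)", TRUE,
                                c(n = n)))
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    list(rho = rho,
         test = new_test_result(rho, p, "Spearman (t approximation)", FALSE,
                                c(n = n)))
  }
}

#' Between-organ Spearman correlation matrix of litter-mean loads
#'
#' The compartmental correlation analysis: for every pair of organs, the
#' Spearman correlation of litter-mean loads across dams (within the given
#' group), with exact permutation p-values at small n.
#'
#' @param litter Litter-level table from [pool_by_dam()].
#' @param group Group to analyse (default the exposed group, i.e. the second
#'   level); `NULL` uses all dams.
#' @return Tibble `organ_a`, `organ_b`, `rho`, `p_value`; the square matrix
#'   is attached as attribute `matrix`.
#' @export
cp_correlation <- function(litter, group = NULL) {
  if (!is.null(group)) litter <- litter[litter$group == group, ]
  wide <- tidyr::pivot_wider(litter[, c("dam_id", "organ", "cp_load")],
                             names_from = "organ", values_from = "cp_load")
  organs <- setdiff(names(wide), "dam_id")
  pairs <- utils::combn(organs, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    s <- spearman_exact(wide[[a]], wide[[b]])
    tibble::tibble(organ_a = a, organ_b = b, rho = s$rho,
                   p_value = s$test$p_value)
  })
  m <- diag(1, length(organs))
  dimnames(m) <- list(organs, organs)
  for (k in seq_len(nrow(res))) {
    m[res$organ_a[k], res$organ_b[k]] <- res$rho[k]
    m[res$organ_b[k], res$organ_a[k]] <- res$rho[k]
  }
  attr(res, "matrix") <- m
  res
}

# Dunn's pairwise post-hoc z-tests on mean ranks after Kruskal-Wallis,
# with tie correction and Bonferroni adjustment.
dunn_posthoc <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  nn <- length(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (nn - 1))
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  purrr::map_dfr(seq_len(m), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((nn * (nn + 1) / 12 - tie_term) * (1 / ni[[a]] + 1 / ni[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    tibble::tibble(group_a = a, group_b = b, z = z,
                   p_value = min(1, 2 * stats::pnorm(-abs(z))),
                   p_adjusted = min(1, m * 2 * stats::pnorm(-abs(z))))
  })
}

#' Within-litter exchangeability check before pooling
#'
#' For each exposure group and organ, tests whether fetuses from different
#' litters of that group differ in load (Kruskal-Wallis across dams) with
#' Dunn's pairwise post-hoc z-tests on mean ranks, Bonferroni-adjusted.
#' Pooling per dam is only warranted when no within-group difference is
#' detected; each group-by-organ family gets a `pooling_permitted` verdict:
#' the omnibus Kruskal-Wallis p must be at least `alpha` and no
#' Bonferroni-adjusted Dunn pair may fall below it (the omnibus gate
#' matters because the fully adjusted pairwise tests alone are underpowered
#' at typical litter sizes).
#'
#' @param study Fetus-level study table (`dam_id`, `group`, `organ`,
#'   `cp_load`).
#' @param alpha Significance level of the verdict.
#' @return Tibble with one row per group and organ: Kruskal-Wallis statistic
#'   and p, minimum Dunn-adjusted p, and the verdict; the pairwise tables
#'   are in the list-column `dunn`.
#' @export
within_litter_check <- function(study, alpha = 0.05) {
  stopifnot(all(c("dam_id", "group", "organ", "cp_load") %in% names(study)))
  study |>
    dplyr::group_by(.data$group, .data$organ) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$dam_id)) < 2 || nrow(d) < 3) {
        stop("within-litter check needs >=2 fetuses in >=2 litters",
             call. = FALSE)
      }
      kw <- stats::kruskal.test(d$cp_load, factor(d$dam_id))
      dn <- dunn_posthoc(d$cp_load, d$dam_id)
      tibble::tibble(
        kw_statistic = unname(kw$statistic),
        kw_p = kw$p.value,
        min_dunn_p = min(dn$p_adjusted),
        pooling_permitted = kw$p.value >= alpha &&
          min(dn$p_adjusted) >= alpha,
        dunn = list(dn)
      )
    }) |>
    dplyr::ungroup()
}

#' Exposure fold-changes per organ
#'
#' The exposed-to-control ratio of group means (or medians) of litter-mean
#' loads, organ by organ, with the exact Mann-Whitney p-value of the group
#' comparison attached.
#'
#' @param litter Litter-level table from [pool_by_dam()].
#' @param fold_stat `"mean"` (default) or `"median"`.
#' @return Tibble per organ: group summaries, `fold_change`, `u`, `p_value`.
#' @export
fold_changes <- function(litter, fold_stat = c("mean", "median")) {
  fold_stat <- match.arg(fold_stat)
  groups <- levels(factor(litter$group))
  if (length(groups) != 2) stop("both groups must be present", call. = FALSE)
  fun <- if (fold_stat == "mean") mean else stats::median
  litter |>
    dplyr::group_by(.data$organ) |>
    dplyr::group_modify(function(d, key) {
      ctrl <- d$cp_load[d$group == groups[1]]
      expo <- d$cp_load[d$group == groups[2]]
      if (fun(ctrl) <= 0) stop("zero control mean", call. = FALSE)
      mw <- mann_whitney_exact(expo, ctrl)
      tibble::tibble(
        control = fun(ctrl), exposed = fun(expo),
        fold_change = fun(expo) / fun(ctrl),
        u = mw$statistic, p_value = mw$p_value,
        n_control = length(ctrl), n_exposed = length(expo)
      )
    }) |>
    dplyr::ungroup()
}

#' Organ load deficits relative to the placenta (exposed group)
#'
#' For each fetal organ, `1 - mean(organ) / mean(placenta)` over the exposed
#' litter means — the fraction of the placental load not reaching the organ
#' — with the exact paired Wilcoxon p-value of the per-dam organ-vs-placenta
#' contrast.
#'
#' @param litter Litter-level table; only the `group` rows are used.
#' @param group Exposed group label (default the second factor level).
#' @return Tibble per fetal organ: `deficit`, `w`, `p_value`, `n_dams`.
#' @export
organ_deficits <- function(litter, group = NULL) {
  if (is.null(group)) group <- levels(factor(litter$group))[2]
  d <- litter[litter$group == group, ]
  wide <- tidyr::pivot_wider(d[, c("dam_id", "organ", "cp_load")],
                             names_from = "organ", values_from = "cp_load")
  if (!"placenta" %in% names(wide)) {
    stop("placenta rows missing", call. = FALSE)
  }
  organs <- setdiff(names(wide), c("dam_id", "placenta"))
  purrr::map_dfr(organs, function(o) {
    wt <- wilcoxon_signed_rank_exact(wide$placenta, wide[[o]])
    tibble::tibble(
      organ = o,
      deficit = 1 - mean(wide[[o]]) / mean(wide$placenta),
      w = wt$statistic, p_value = wt$p_value, n_dams = nrow(wide)
    )
  })
}

#' Group comparison table with median (Q1; Q3) display
#'
#' Per-organ two-group comparison on litter means: quartile summaries per
#' group plus the exact Mann-Whitney test.
#'
#' @param litter Litter-level table.
#' @return Tibble per organ.
#' @export
group_comparison <- function(litter) {
  groups <- levels(factor(litter$group))
  litter |>
    dplyr::group_by(.data$organ) |>
    dplyr::group_modify(function(d, key) {
      ctrl <- d$cp_load[d$group == groups[1]]
      expo <- d$cp_load[d$group == groups[2]]
      mw <- mann_whitney_exact(expo, ctrl)
      tibble::tibble(
        control_label = quartile_summary(ctrl)$label,
        exposed_label = quartile_summary(expo)$label,
        u = mw$statistic, p_value = mw$p_value
      )
    }) |>
    dplyr::ungroup()
}
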