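test_that("median (Q1; Q3) summaries use the interpolation convention", {
  s <- quartile_summary(c(1, 2, 3, 4, 5))
  expect_equal(c(s$median, s$q1, s$q3), c(3, 2, 4))
  s1 <- quartile_summary(7)
  expect_equal(c(s1$median, s1$q1, s1$q3), c(7, 7, 7))
  expect_error(quartile_summary(numeric(0)), "empty")
})

test_that("exact Mann-Whitney matches enumeration and reference values", {
  # complete separation at 7 vs 7: the two extreme labelings out of 3432
  x <- 101:107; y <- 1:7
  r <- mann_whitney_exact(x, y)
  expect_true(r$exact)
  expect_equal(r$p_value, 2 / 3432, tolerance = 1e-12)
  expect_equal(r$statistic, 49)

  # identical tied groups: maximal overlap
  r2 <- mann_whitney_exact(1:7, 1:7)
  expect_equal(r2$statistic, 24.5)
  expect_equal(r2$p_value, 1)

  # random data without ties: agrees with the exact reference distribution
  set.seed(101)
  for (i in 1:8) {
    x <- rnorm(6); y <- rnorm(7, 0.5)
    r <- mann_whitney_exact(x, y)
    expect_equal(r$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
    expect_equal(r$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
  }
  # with ties: agrees with the independent enumeration oracle
  xt <- c(1, 2, 2, 3, 5); yt <- c(2, 3, 3, 4, 6)
  expect_equal(mann_whitney_exact(xt, yt)$p_value, oracle_mw_p(xt, yt),
               tolerance = 1e-12)
})

test_that("exact signed-rank test matches enumeration", {
  x <- c(5, 6, 7, 8, 9, 10, 11); y <- x - 1   # all positive differences
  r <- wilcoxon_signed_rank_exact(x, y)
  expect_equal(r$statistic, 28)
  expect_equal(r$p_value, 2 / 128, tolerance = 1e-12)

  # mirrored differences: perfectly balanced
  d <- c(1, -1, 2, -2, 3, -3)
  r2 <- wilcoxon_signed_rank_exact(d, rep(0, 6))
  expect_equal(r2$p_value, 1)

  set.seed(102)
  for (i in 1:8) {
    x <- rnorm(7); y <- rnorm(7, 0.3)
    expect_equal(wilcoxon_signed_rank_exact(x, y)$p_value,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(wilcoxon_signed_rank_exact(x, y)$p_value,
                 oracle_wsr_p(x, y), tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank_exact(1:4, 1:4), "zero")
})

test_that("exact Spearman matches the permutation distribution", {
  x <- 1:7; y <- c(2, 4, 6, 8, 10, 12, 14)
  s <- spearman_exact(x, y)
  expect_equal(s$rho, 1)
  expect_equal(s$test$p_value, 2 / 5040, tolerance = 1e-12)
  s2 <- spearman_exact(x, rev(y))
  expect_equal(s2$rho, -1)

  set.seed(103)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    s <- spearman_exact(x, y)
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(s$test$p_value, ct$p.value, tolerance = 1e-12)
  }
  flat <- spearman_exact(rep(1, 5), 1:5)
  expect_true(is.na(flat$rho))
})

test_that("two-group Kruskal-Wallis collapses to the rank-sum z statistic", {
  set.seed(104)
  x <- rnorm(6); y <- rnorm(5, 1)
  kw <- kruskal.test(c(x, y), factor(rep(1:2, c(6, 5))))
  # force the normal approximation of the rank-sum test
  mw <- mann_whitney_exact(x, y, max_enumerate = 1)
  z <- qnorm(mw$p_value / 2)
  expect_equal(unname(kw$statistic), z^2, tolerance = 1e-9)
})

test_that("within-litter check permits pooling for exchangeable fetuses", {
  set.seed(105)
  verdicts <- replicate(60, {
    tb <- tibble::tibble(
      dam_id = rep(paste0("d", 1:7), each = 4),
      group = "DE", organ = "placenta",
      cp_load = rlnorm(28, log(1e4), 0.3))
    all(within_litter_check(tb)$pooling_permitted)
  })
  expect_gte(mean(verdicts), 0.9)

  # a litter shifted tenfold is caught (three litters of five: the regime
  # where a rank test across litters has power)
  tb <- tibble::tibble(
    dam_id = rep(paste0("d", 1:3), each = 5),
    group = "DE", organ = "placenta",
    cp_load = rlnorm(15, log(1e4), 0.2) *
      rep(c(10, 1, 1), each = 5))
  expect_false(all(within_litter_check(tb)$pooling_permitted))
  expect_error(within_litter_check(
    tibble::tibble(dam_id = "d1", group = "C", organ = "heart",
                   cp_load = 1:3)))
})

test_that("fold changes and deficits are litter-mean arithmetic", {
  lt <- tidyr::expand_grid(dam_id = paste0("d", 1:14), organ = "placenta")
  lt$group <- factor(rep(c("C", "DE"), each = 7), levels = c("C", "DE"))
  lt$cp_load <- ifelse(lt$group == "C", 100, 410)
  fc <- fold_changes(lt)
  expect_equal(fc$fold_change, 4.1, tolerance = 1e-12)
  expect_lt(fc$p_value, 0.001)
  lt$cp_load <- 100
  expect_equal(fold_changes(lt)$fold_change, 1)

  wide <- tidyr::expand_grid(dam_id = paste0("d", 1:7),
                             organ = c("placenta", "gonad"))
  wide$group <- factor("DE", levels = c("C", "DE"))
  wide$cp_load <- ifelse(wide$organ == "placenta", 100, 28) +
    rep(rnorm(7, 0, 1e-6), each = 2)
  od <- organ_deficits(wide, group = "DE")
  expect_equal(od$deficit, 0.72, tolerance = 1e-4)
  expect_equal(od$p_value, 2 / 128, tolerance = 1e-9)
  wide$cp_load <- 100 + rnorm(14, 0, 1e-8)
  expect_equal(organ_deficits(wide, group = "DE")$deficit, 0,
               tolerance = 1e-6)
})

test_that("fold changes and deficits only see litter means", {
  sim <- simulate_study(study_design(n_dams_per_group = 4),
                        imaging = tiny_imaging(), seed = 107)
  st <- truth_as_study(sim)
  # relabel fetuses within each dam
  st2 <- st |>
    dplyr::group_by(.data$dam_id, .data$organ) |>
    dplyr::mutate(cp_load = sample(.data$cp_load)) |>
    dplyr::ungroup()
  f1 <- fold_changes(pool_by_dam(st))
  f2 <- fold_changes(pool_by_dam(st2))
  expect_equal(f1$fold_change, f2$fold_change, tolerance = 1e-12)
  d1 <- organ_deficits(pool_by_dam(st))
  d2 <- organ_deficits(pool_by_dam(st2))
  expect_equal(d1$deficit, d2$deficit, tolerance = 1e-12)
})

test_that("placenta-gonad contrast is detected in most simulated studies", {
  set.seed(108)
  hits <- replicate(30, {
    sim <- simulate_study(imaging = tiny_imaging(), seed = NULL)
    lt <- pool_by_dam(truth_as_study(sim))
    wide <- tidyr::pivot_wider(
      lt[lt$group == "DE", c("dam_id", "organ", "cp_load")],
      names_from = "organ", values_from = "cp_load")
    wilcoxon_signed_rank_exact(wide$placenta, wide$gonad)$p_value <= 0.05
  })
  expect_gte(mean(hits), 0.9)
})
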