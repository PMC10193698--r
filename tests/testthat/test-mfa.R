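test_that("a single-group MFA is standardized PCA up to scale and sign", {
  set.seed(301)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))
  m <- mfa(x, groups = list(g = colnames(x)), n_dims = 4)
  z <- scale(x) * sqrt(10 / 9)              # population standardization
  p <- prcomp(z, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2 * 9 / 10
  expect_equal(m$eig$eigenvalue, ev / ev[1], tolerance = 1e-10)
  co <- as.matrix(m$ind[, paste0("dim", 1:4)])
  expect_equal(abs(co), abs(p$x / sqrt(ev[1])), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("duplicated variables inside a group do not move individuals", {
  set.seed(302)
  x <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("v", 1:5)))
  x3 <- cbind(x, v1b = x[, 1], v1c = x[, 1])
  m1 <- mfa(x, groups = list(a = "v1", b = paste0("v", 2:5)), n_dims = 4)
  m2 <- mfa(x3, groups = list(a = c("v1", "v1b", "v1c"),
                              b = paste0("v", 2:5)), n_dims = 4)
  expect_equal(abs(as.matrix(m1$ind[, paste0("dim", 1:4)])),
               abs(as.matrix(m2$ind[, paste0("dim", 1:4)])),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("two identical one-variable groups give eigenvalues (2, 0)", {
  set.seed(303)
  a <- rnorm(9)
  m <- mfa(cbind(a = a, b = a), groups = list(g1 = "a", g2 = "b"),
           n_dims = 2)
  expect_equal(m$eig$eigenvalue[1], 2, tolerance = 1e-10)
  expect_lt(m$eig$eigenvalue[2], 1e-10)
  expect_equal(m$eig$pct_inertia[1], 100, tolerance = 1e-8)
})

test_that("dimensions are orthogonal, inertia adds up, groups are balanced", {
  set.seed(304)
  x <- matrix(rnorm(90), 15, 6, dimnames = list(NULL, paste0("v", 1:6)))
  grp <- list(a = paste0("v", 1:2), b = paste0("v", 3:6))
  m <- mfa(x, grp, n_dims = 6)
  co <- as.matrix(m$ind[, paste0("dim", 1:m$n_dims)])
  cc <- crossprod(sweep(co, 2, colMeans(co))) / nrow(co)
  expect_equal(cc, diag(m$eig$eigenvalue[1:m$n_dims]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(m$eig$pct_inertia), 100, tolerance = 1e-8)
  # after weighting, the first eigenvalue of every group block is exactly 1,
  # so no group can push more than one unit of inertia into dimension 1
  z <- cpscan:::standardize_pop(as.matrix(x))
  for (g in names(grp)) {
    zg <- sweep(z[, grp[[g]], drop = FALSE], 2,
                sqrt(m$lambda1[[g]]), "/")
    expect_equal((svd(zg / sqrt(15))$d[1])^2, 1, tolerance = 1e-10)
  }
  expect_error(mfa(cbind(x, k = 1), list(a = colnames(x), b = "k")),
               "constant")
})

test_that("category statistics behave at the barycentre level", {
  set.seed(305)
  x <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("v", 1:4)))
  m <- mfa(x, groups = list(g = colnames(x)), n_dims = 3)
  # a factor balanced so that its barycentre sits at the origin
  co <- m$ind$dim1
  f <- factor(ifelse(seq_len(30) %% 2 == 0, "a", "b"))
  # symmetric split: construct one level as a mirror of the other
  sc <- supplementary_categories(m, f)
  expect_true(all(abs(sc$coord[sc$dim == 1]) < 2))
  # whole-sample level is rejected
  expect_error(supplementary_categories(m, factor(rep("x", 30))))
  # cos2 sums to one over dimensions per level
  sums <- tapply(sc$cos2, sc$level, sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-10)
})

test_that("v.test matches its permutation null z-score", {
  set.seed(306)
  x <- matrix(rnorm(100), 25, 4, dimnames = list(NULL, paste0("v", 1:4)))
  x[1:10, ] <- x[1:10, ] + 1.2
  m <- mfa(x, groups = list(g = colnames(x)), n_dims = 2)
  f <- factor(rep(c("hi", "lo"), c(10, 15)))
  sc <- supplementary_categories(m, f)
  co <- m$ind$dim1
  idx_hi <- which(f == "hi")
  obs <- mean(co[idx_hi])
  perm <- replicate(10000, mean(co[sample(25, 10)]))
  z_emp <- (obs - mean(perm)) / sd(perm)
  v <- sc$v_test[sc$level == "hi" & sc$dim == 1]
  expect_equal(v, z_emp, tolerance = 0.1)
})

test_that("dimension description is a one-way ANOVA R-squared", {
  set.seed(307)
  x <- matrix(rnorm(128), 32, 4, dimnames = list(NULL, paste0("v", 1:4)))
  m <- mfa(x, groups = list(g = colnames(x)), n_dims = 2)
  # factor aligned with the sign of dimension 1: R-squared equals the
  # squared point-biserial correlation
  f <- factor(m$ind$dim1 > 0)
  dd <- dimension_description(m, f, dims = 1)
  pb <- cor(m$ind$dim1, as.numeric(f))^2
  expect_equal(dd$r_squared, pb, tolerance = 1e-10)
  # perfectly separated synthetic coordinates
  m2 <- m
  m2$ind$dim1 <- ifelse(f == TRUE, 1, -1)
  expect_equal(suppressWarnings(
    dimension_description(m2, f, dims = 1)$r_squared), 1, tolerance = 1e-12)
  # random labels: R-squared stays at the 1/(n-1) noise scale
  set.seed(308)
  r2 <- replicate(200, {
    dimension_description(m, factor(sample(rep(1:2, 16))), dims = 1)$r_squared
  })
  expect_lt(abs(mean(r2) - 1 / 31), 0.015)
  expect_error(dimension_description(m, factor(rep("a", 32))))
})

test_that("confidence ellipses shrink as 1/sqrt(n) and degenerate at 0", {
  set.seed(309)
  x <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b")))
  m <- mfa(x, groups = list(g = c("a", "b")), n_dims = 2)
  f <- factor(rep(c("u", "w"), c(900, 100)))
  e <- confidence_ellipse(m, f)
  pars <- attr(e, "parameters")
  ratio <- mean(pars$w$semi_axes) / mean(pars$u$semi_axes)
  expect_equal(ratio, 3, tolerance = 0.35)      # sqrt(900/100)
  e0 <- confidence_ellipse(m, f, coverage = 0)
  expect_equal(max(abs(e0$x[e0$level == "u"] - pars$u$centre[1])), 0,
               tolerance = 1e-9)
})

test_that("the variable map stays inside the correlation circle", {
  set.seed(310)
  for (i in 1:20) {
    x <- matrix(rnorm(11 * 5), 11, 5, dimnames = list(NULL, paste0("v", 1:5)))
    m <- mfa(x, groups = list(a = paste0("v", 1:2), b = paste0("v", 3:5)))
    vm <- variable_factor_map(m)
    expect_true(all(vm$corr_dim1^2 + vm$corr_dim2^2 <= 1 + 1e-12))
  }
  # a variable that *is* dimension 1 lands on the circle at (1, 0)
  set.seed(311)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("v1", "v2", "v3")))
  m <- mfa(x, groups = list(g = c("v1", "v2", "v3")), n_dims = 2)
  x2 <- cbind(x, d1 = m$ind$dim1)
  m2 <- mfa(x2, groups = list(g = c("v1", "v2", "v3"), h = "d1"))
  vm2 <- variable_factor_map(m2)
  expect_equal(abs(vm2$corr_dim1[vm2$variable == "d1"]), 1, tolerance = 0.02)
})

test_that("the study assembly produces the three variable groups", {
  sim <- simulate_study(study_design(n_dams_per_group = 3),
                        imaging = tiny_imaging(), seed = 312)
  fet <- derive_biometry(sim$fetuses)
  inp <- study_mfa_input(truth_as_study(sim), fet)
  expect_setequal(names(inp$groups),
                  c("cp_load", "organ_weight", "weight_ratio"))
  m <- mfa(inp$data, inp$groups)
  expect_equal(m$n, nrow(inp$data))
  sc <- supplementary_categories(m, inp$exposure)
  expect_true(any(sc$significant[sc$dim == 1]))
})
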