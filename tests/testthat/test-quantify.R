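test_that("tissue segmentation recovers the true tissue area", {
  set.seed(20)
  img <- tiny_imaging(176)
  rel_err <- replicate(12, {
    m <- cpscan:::make_tissue_mask(176, 0.8)
    tile <- render_tile(matrix(numeric(0), 0, 2), img, mask = m)
    seg <- segment_tissue(tile)
    abs(attr(seg, "area_mm2") - mask_area(m, 0.83)) / mask_area(m, 0.83)
  })
  expect_lt(mean(rel_err), 0.05)
  expect_true(all(rel_err < 0.10))
})

test_that("segmentation survives saturating particles inside the tissue", {
  set.seed(21)
  img <- tiny_imaging(128)
  m <- cpscan:::make_tissue_mask(128, 0.8)
  idx <- sample(which(m), 40, replace = TRUE)
  cent <- cbind(((idx - 1) %% 128) + 1, ((idx - 1) %/% 128) + 1)
  tile <- render_tile(cent, img, mask = m)
  seg <- segment_tissue(tile)
  expect_lt(abs(attr(seg, "area_mm2") / mask_area(m, 0.83) - 1), 0.10)
})

test_that("blank and full tiles hit their degenerate limits", {
  blank <- tile_scan(matrix(0, 64, 64), matrix(0, 64, 64), 0.83)
  seg <- segment_tissue(blank)
  expect_equal(attr(seg, "area_mm2"), 0)
  expect_error(load_per_mm3(0, attr(seg, "area_mm2")), "positive")

  img <- tiny_imaging(512)
  set.seed(22)
  full <- render_tile(matrix(numeric(0), 0, 2), img, tissue_fraction = 1)
  seg_full <- segment_tissue(full)
  expect_equal(attr(seg_full, "area_mm2"), (512 * 0.83e-3)^2,
               tolerance = 1e-10)
  expect_equal(attr(seg_full, "area_mm2"), 0.1806, tolerance = 1e-3)
})

test_that("volumetric conversion follows the closed form", {
  expect_equal(load_per_mm3(10, 1.0, 7), 10 / 7e-3, tolerance = 1e-12)
  expect_equal(load_per_mm3(10, 1.0, 7), 1428.571, tolerance = 1e-4)
  expect_equal(load_per_mm3(21, 3.0, 7), 1000, tolerance = 1e-12)
  expect_equal(load_per_mm3(0, 2.5), 0)
  expect_error(load_per_mm3(5, 0))
})

test_that("sample aggregation averages regions and flags under-sampling", {
  a <- aggregate_sample(c(100, 200, 300, 400, 500))
  expect_equal(a$sample_load, 300)
  expect_false(a$flagged)
  b <- aggregate_sample(c(100, 200))
  expect_equal(b$sample_load, 150)
  expect_true(b$flagged)
  expect_warning(cc <- aggregate_sample(c(100, 200, 300, 400, NA)),
                 "excluded")
  expect_equal(cc$sample_load, 250)
  expect_equal(cc$n_regions, 4)
  expect_error(suppressWarnings(aggregate_sample(NA_real_)), "no valid")
  # pooled alternative weights regions by area
  p <- aggregate_sample(method = "pooled", counts = c(10, 0),
                        areas_mm2 = c(1, 1), thickness_um = 7)
  expect_equal(p$sample_load, 10 / (2 * 7e-3))
})

test_that("litter pooling averages fetuses and is idempotent", {
  tb <- tibble::tibble(
    dam_id = rep(c("d1", "d2"), each = 3),
    group = "C", organ = "heart",
    cp_load = c(10, 20, 30, 5, 5, 5))
  pooled <- pool_by_dam(tb)
  expect_equal(pooled$cp_load, c(20, 5))
  expect_equal(pooled$n_fetuses, c(3L, 3L))
  again <- pool_by_dam(pooled)
  expect_equal(again$cp_load, pooled$cp_load)
  # shape contract on a full study
  sim <- simulate_study(study_design(n_dams_per_group = 3),
                        imaging = tiny_imaging(), seed = 3)
  lt <- pool_by_dam(truth_as_study(sim))
  expect_equal(nrow(lt), 2 * 3 * 6)
})

test_that("biometry ratios sit on their display scales and are consistent", {
  f <- tibble::tibble(fetal_weight_g = 36, placenta_g = 7.4,
                      heart_g = 0.20, kidney_g = 0.17,
                      liver_g = 2.4, lung_g = 0.98)
  # ratios use the fetal weight as denominator, on display scales
  f2 <- derive_biometry(f)
  expect_equal(f2$placental_efficiency, 36 / 7.4, tolerance = 1e-12)
  expect_equal(f2$placental_efficiency, 4.86, tolerance = 1e-2)
  expect_equal(f2$placenta_fetus_ratio_x10, 2.06, tolerance = 1e-2)
  expect_equal(f2$placental_efficiency * f2$placenta_fetus_ratio_x10 / 10, 1,
               tolerance = 1e-12)
  f3 <- derive_biometry(tibble::tibble(fetal_weight_g = 35, placenta_g = 7,
                                       heart_g = 0.20))
  expect_equal(f3$heart_fetus_ratio_x1e3, 5.71, tolerance = 1e-2)
  expect_error(derive_biometry(tibble::tibble(fetal_weight_g = 36,
                                              placenta_g = 0)), "positive")
})

test_that("expected loads are invariant to tile size at fixed density", {
  # the same density measured at two tile sizes gives the same load
  set.seed(25)
  est <- sapply(c(96, 192), function(np) {
    img <- imaging_config(tile_pixels = np)
    vol <- (np * 0.83e-3)^2 * 7e-3
    loads <- replicate(30, {
      m <- matrix(TRUE, np, np)
      n <- rpois(1, 2.5e4 * vol)
      if (n > 0) {
        idx <- sample(length(m), n)
        cent <- cbind(((idx - 1) %% np) + 1, ((idx - 1) %/% np) + 1)
      } else cent <- matrix(numeric(0), 0, 2)
      tile <- render_tile(cent, img, mask = m)
      load_per_mm3(call_particles(tile)$n, mask_area(m, 0.83))
    })
    mean(loads)
  })
  expect_lt(abs(est[1] / est[2] - 1), 0.25)
})
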