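test_that("channel thresholds are fractions of the per-tile maximum", {
  ch <- matrix(c(rep(100, 98), 2000, 1500), 10, 10)
  m <- channel_threshold(ch, 0.995)
  expect_equal(attr(m, "threshold"), 1990)
  expect_equal(sum(m), 1)
  ch2 <- matrix(c(rep(100, 99), 1200), 10, 10)
  m2 <- channel_threshold(ch2, 0.55)
  expect_equal(attr(m2, "threshold"), 660)
  # all-equal nonzero image: every pixel ties at the maximum and passes
  m3 <- channel_threshold(matrix(7, 5, 5), 0.9)
  expect_true(all(m3))
  expect_warning(channel_threshold(matrix(0, 4, 4), 0.5), "constant-zero")
})

test_that("noise-free planted particles are called exactly at their centres", {
  img <- tiny_imaging()
  set.seed(10)
  cent <- separated_centroids(5, 96)
  tile <- render_tile(cent, img, noise = FALSE, tissue_fraction = 0.95)
  calls <- call_particles(tile)
  expect_equal(calls$n, 5)
  got <- as.matrix(calls$particles[, c("row", "col")])
  d <- sapply(seq_len(5), function(i) {
    min(sqrt(rowSums(sweep(got, 2, cent[i, ])^2)))
  })
  expect_true(all(d <= 0.75))
})

test_that("bright single-channel structures are never called", {
  # collagen-like object: bright in the narrow channel only, sitting in
  # ordinary tissue whose level is below 55% of the broad-channel maximum
  img <- tiny_imaging()
  narrow <- matrix(3, 96, 96); narrow[40:50, 20] <- 2000
  broad <- matrix(120, 96, 96); broad[80:82, 80:82] <- 300
  tile <- tile_scan(narrow, broad, 0.83)
  expect_equal(call_particles(tile)$n, 0)

  # rendered collagen never co-saturates the broad channel
  set.seed(12)
  t2 <- render_tile(matrix(numeric(0), 0, 2),
                    tiny_imaging(collagen_per_mm2 = 400), noise = FALSE)
  expect_lt(max(t2$broad), 0.3 * 4095)
})

test_that("diagonally touching components split under 4-connectivity", {
  narrow <- matrix(0, 12, 12); broad <- matrix(0, 12, 12)
  blobs <- rbind(c(3, 3), c(4, 4), c(5, 5))  # diagonal chain
  for (k in seq_len(nrow(blobs))) {
    narrow[blobs[k, 1], blobs[k, 2]] <- 4095
    broad[blobs[k, 1], blobs[k, 2]] <- 4095
  }
  tile <- tile_scan(narrow, broad, 0.83)
  expect_equal(call_particles(tile, detection_params(connectivity = 8))$n, 1)
  expect_equal(call_particles(tile, detection_params(connectivity = 4))$n, 3)
})

test_that("sparse labelling agrees with independent reference labellers", {
  same_partition <- function(a, b) {
    length(unique(a)) == length(unique(b)) &&
      all(tapply(b, a, function(v) length(unique(v))) == 1) &&
      all(tapply(a, b, function(v) length(unique(v))) == 1)
  }
  set.seed(77)
  for (i in 1:20) {
    m <- matrix(runif(40 * 40) < 0.12, 40, 40)
    px <- which(m)
    rows <- ((px - 1) %% 40) + 1
    cols <- ((px - 1) %/% 40) + 1
    # 4-connectivity against the dense labeller in EBImage
    lab4 <- cpscan:::label_sparse(rows, cols, 40, connectivity = 4)
    ref4 <- EBImage::bwlabel(m)[cbind(rows, cols)]
    expect_true(same_partition(lab4, ref4))
    # 8-connectivity against a graph-components oracle
    np <- length(px)
    d2 <- as.matrix(dist(cbind(rows, cols)))
    adj <- d2 > 0 & d2 < 1.5  # kings-move neighbours
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    ref8 <- igraph::components(g)$membership
    lab8 <- cpscan:::label_sparse(rows, cols, 40, connectivity = 8)
    expect_true(same_partition(lab8, ref8))
  }
})

test_that("lowering the broad fraction never shrinks the intersection", {
  set.seed(13)
  img <- tiny_imaging()
  cent <- separated_centroids(4, 96)
  tile <- render_tile(cent, img)
  strict <- call_particles(tile, detection_params(broad_fraction = 0.75))
  loose <- call_particles(tile, detection_params(broad_fraction = 0.40))
  expect_gte(sum(loose$particles$n_px), sum(strict$particles$n_px))
  # count is non-decreasing as min_component_px decreases
  n2 <- call_particles(tile, detection_params(min_component_px = 3))$n
  n1 <- call_particles(tile, detection_params(min_component_px = 1))$n
  expect_gte(n1, n2)
})

test_that("calls are invariant under 90-degree rotation of both channels", {
  set.seed(14)
  img <- tiny_imaging()
  tile <- render_tile(separated_centroids(6, 96), img)
  rot <- function(m) t(m)[, nrow(m):1]  # 90 deg counter-clockwise
  tile_r <- tile_scan(rot(tile$narrow), rot(tile$broad), 0.83)
  a <- call_particles(tile)
  b <- call_particles(tile_r)
  expect_equal(b$n, a$n)
  expect_equal(as.integer(sort(b$particles$n_px)),
               as.integer(sort(a$particles$n_px)))
})

test_that("precision and recall stay above 0.99 at default noise", {
  set.seed(15)
  img <- imaging_config()       # native default: 512 px tiles
  density <- 1e4                # particles per mm^3
  vol <- (512 * 0.83e-3)^2 * 7e-3
  tp <- fp <- fn <- 0
  for (i in 1:12) {
    m <- cpscan:::make_tissue_mask(512, 0.9)
    n <- rpois(1, density * vol * 0.9)
    idx <- sample(which(m), n, replace = TRUE)
    cent <- cbind(((idx - 1) %% 512) + 1, ((idx - 1) %/% 512) + 1)
    tile <- render_tile(cent, img, mask = m)
    calls <- call_particles(tile)
    got <- as.matrix(calls$particles[, c("row", "col")])
    used <- rep(FALSE, nrow(got))
    for (k in seq_len(n)) {
      if (!nrow(got)) { fn <- fn + 1; next }
      d2 <- rowSums(sweep(got, 2, cent[k, ])^2)
      j <- which.min(ifelse(used, Inf, d2))
      if (length(j) && d2[j] <= 4) { tp <- tp + 1; used[j] <- TRUE }
      else fn <- fn + 1
    }
    fp <- fp + sum(!used)
  }
  expect_gte(tp / (tp + fn), 0.99)
  expect_gte(tp / (tp + fp), 0.99)
})

test_that("embedment verification classifies planted particles", {
  img <- tiny_imaging()
  set.seed(16)
  z <- render_zstack(data.frame(row = c(30, 60), col = c(30, 60),
                                depth_um = c(3.5, 0),
                                surface = c(FALSE, TRUE)),
                     img, n_slices = 12)
  expect_equal(as.character(verify_embedment(z, c(30, 30))), "embedded")
  expect_equal(as.character(verify_embedment(z, c(60, 60))), "surface")
  expect_equal(as.character(verify_embedment(z, c(85, 15))), "indeterminate")
  expect_error(verify_embedment(z, c(500, 10)), "outside")
})
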