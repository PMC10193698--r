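# Shared fixtures: everything is generated in code at test time.

# small imaging geometry for fast unit tests
tiny_imaging <- function(tile_pixels = 96, ...) {
  imaging_config(tile_pixels = tile_pixels, ...)
}

# n particle centres with pairwise separation >= min_sep, away from edges
separated_centroids <- function(n, tile, min_sep = 12, margin = 8) {
  pts <- matrix(numeric(0), 0, 2)
  guard <- 0
  while (nrow(pts) < n && guard < 5000) {
    cand <- cbind(runif(1, margin, tile - margin),
                  runif(1, margin, tile - margin))
    if (!nrow(pts) ||
        min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_sep) {
      pts <- rbind(pts, cand)
    }
    guard <- guard + 1
  }
  pts
}

# independent brute-force two-sided Mann-Whitney p by enumeration over
# labelings (written differently from the package's implementation)
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[1:n]) - n * (n + 1) / 2
  cmb <- combn(n + m, n)
  us <- apply(cmb, 2, function(ix) sum(r[ix])) - n * (n + 1) / 2
  mean(abs(us - n * m / 2) >= abs(u_obs - n * m / 2) - 1e-9)
}

# independent signed-rank enumeration
oracle_wsr_p <- function(x, y) {
  d <- (x - y); d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  cen <- sum(r) / 2
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  ws <- apply(grid, 1, function(s) sum(r[as.logical(s)]))
  mean(abs(ws - cen) >= abs(w_obs - cen) - 1e-9)
}

# fetus-level ground-truth table reshaped as a measured study
# (cp_load := true density), for render-free statistical tests
truth_as_study <- function(sim) {
  s <- sim$study
  s$cp_load <- s$true_density
  s
}
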