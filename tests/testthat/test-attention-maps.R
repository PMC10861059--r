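test_that("binary fixation maps use set semantics", {
  expect_equal(sum(build_binary_fixation_map(NULL, c(10, 10))), 0)
  m <- build_binary_fixation_map(data.frame(x = 3, y = 4), c(10, 10))
  expect_equal(sum(m), 1)
  expect_equal(m[5, 4], 1)  # 0-based (x=3, y=4) -> [row 5, col 4]
  # coincident centroids still give a single cell of value 1
  m2 <- build_binary_fixation_map(data.frame(x = c(3, 3), y = c(4, 4)),
                                  c(10, 10))
  expect_equal(sum(m2), 1)
  expect_equal(max(m2), 1)
  # off-map centroids are skipped
  m3 <- build_binary_fixation_map(data.frame(x = c(3, 99), y = c(4, 4)),
                                  c(10, 10))
  expect_equal(sum(m3), 1)
})

test_that("smoothing produces a symmetric unit-mass heatmap", {
  geom <- test_geometry()
  m <- build_binary_fixation_map(data.frame(x = 25, y = 25), c(51, 51))
  sm <- smooth_and_normalise(m, geom, bandwidth_deg = 0.2)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_equal(sm, t(sm), tolerance = 1e-12)           # radial symmetry
  expect_equal(sm[, 51:1], sm, tolerance = 1e-12)
  expect_equal(which.max(sm), which.max(m))
  # two equal fixations mirrored about the vertical midline of a 52-wide
  # map -> each half carries exactly half the mass
  m2 <- build_binary_fixation_map(data.frame(x = c(10, 41), y = c(25, 25)),
                                  c(51, 52))
  sm2 <- smooth_and_normalise(m2, geom, bandwidth_deg = 0.2)
  expect_equal(sum(sm2[, 1:26]), 0.5, tolerance = 1e-9)
  # matches a direct dense-convolution oracle
  sigma <- degrees_to_stimulus_px(0.2, geom)
  r <- ceiling(3 * sigma)
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  oracle <- matrix(0, 51, 52)
  for (idx in which(m2 == 1)) {
    rc <- arrayInd(idx, c(51, 52))
    for (di in -r:r) for (dj in -r:r) {
      ii <- rc[1] + di; jj <- rc[2] + dj
      if (ii >= 1 && ii <= 51 && jj >= 1 && jj <= 52)
        oracle[ii, jj] <- oracle[ii, jj] + K[di + r + 1, dj + r + 1]
    }
  }
  oracle <- oracle / sum(oracle)
  expect_equal(sm2, oracle, tolerance = 1e-12)
})

test_that("all-zero maps pass through smoothing with a warning", {
  geom <- test_geometry()
  z <- matrix(0, 5, 5)
  expect_warning(out <- smooth_and_normalise(z, geom), "all-zero")
  expect_equal(out, z)
  expect_error(smooth_and_normalise(matrix(-1, 2, 2), geom),
               "non-negative")
})

test_that("area-averaging resize preserves means and constants", {
  set.seed(3)
  m <- matrix(runif(72 * 128), 72, 128)
  out <- resize_area(m, c(28, 28))
  expect_equal(dim(out), c(28, 28))
  expect_equal(mean(out), mean(m), tolerance = 1e-12)
  expect_equal(resize_area(matrix(3, 10, 10), c(4, 4)),
               matrix(3, 4, 4), tolerance = 1e-12)
  # integer-factor downscale equals block means
  m2 <- matrix(1:16, 4, 4)
  expect_equal(resize_area(m2, c(2, 2)),
               matrix(c(mean(m2[1:2, 1:2]), mean(m2[3:4, 1:2]),
                        mean(m2[1:2, 3:4]), mean(m2[3:4, 3:4])), 2, 2))
})

test_that("DoF maps match a scalar brute-force oracle on small grids", {
  dof_oracle <- function(neg, pos) {
    I <- matrix(0, nrow(neg), ncol(neg))
    for (i in seq_len(nrow(neg))) for (j in seq_len(ncol(neg)))
      I[i, j] <- neg[i, j] - pos[i, j]
    mu <- sum(I) / length(I)
    s <- sqrt(sum((I - mu)^2) / length(I))
    D <- matrix(0, nrow(I), ncol(I))
    for (i in seq_len(nrow(I))) for (j in seq_len(ncol(I)))
      D[i, j] <- 1 / (1 + exp(-I[i, j] / s))
    D
  }
  set.seed(11)
  for (n in 2:4) {
    a <- matrix(runif(n * n), n); a <- a / sum(a)
    b <- matrix(runif(n * n), n); b <- b / sum(b)
    expect_equal(compute_dof(a, b)$grid, dof_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("DoF is antisymmetric, scale-invariant and 0.5 when degenerate", {
  set.seed(12)
  a <- matrix(runif(25), 5); a <- a / sum(a)
  b <- matrix(runif(25), 5); b <- b / sum(b)
  d <- compute_dof(a, b)
  expect_true(all(d$grid > 0 & d$grid < 1))
  expect_equal(d$grid + compute_dof(b, a)$grid, matrix(1, 5, 5),
               tolerance = 1e-12)
  expect_equal(compute_dof(7 * a, 7 * b)$grid, d$grid, tolerance = 1e-12)
  expect_equal(compute_dof(a, a)$grid, matrix(0.5, 5, 5))
  # cells where the groups tie sit exactly at 0.5
  a2 <- a; b2 <- a; a2[1, 1] <- a[1, 1] + 0.1; b2[2, 2] <- a[2, 2] + 0.1
  d2 <- compute_dof(a2, b2)
  expect_gt(d2$grid[1, 1], 0.5)
  expect_lt(d2$grid[2, 2], 0.5)
  expect_equal(d2$grid[3, 3], 0.5)
  expect_error(compute_dof(a, matrix(0, 2, 2)), "shape")
})

test_that("DoF at a cell increases with reference-group mass at fixed sigma", {
  set.seed(13)
  a <- matrix(runif(16), 4); b <- matrix(runif(16), 4)
  d0 <- compute_dof(a, b)
  sig <- d0$sigma_I
  a2 <- a; a2[2, 3] <- a[2, 3] + 0.05
  I2 <- a2 - b
  d2_fixed_sigma <- 1 / (1 + exp(-I2[2, 3] / sig))
  expect_gt(d2_fixed_sigma, d0$grid[2, 3])
})

test_that("dof_sequence emits one map per frame with sane degenerate cases", {
  stim <- make_stimulus(12, seed = 3)
  geom <- stimulus_geometry(stim)
  spec <- cohort_spec(n_asd = 2, n_td = 2, n_moderate = 2, seed = 4)
  coh <- make_cohort(spec, stim, geom)
  recs <- lapply(coh$recordings, process_recording,
                 cfg = fixation_filter_config(), geometry = geom,
                 n_frames = stim$n_frames, duration_s = stim$duration_s)
  dof <- dof_sequence(recs, "TD", "ASD", stim$n_frames, stim$shape, geom,
                      map_shape = c(7, 7))
  expect_length(dof, stim$n_frames)
  for (d in dof) {
    expect_true(all(d$grid > 0 & d$grid < 1))
    expect_equal(dim(d$grid), c(7, 7))
  }
  # an empty reference group cannot form a difference
  asd_only <- recs[vapply(recs, `[[`, "", "group") == "ASD"]
  expect_error(dof_sequence(asd_only, "TD", "ASD", stim$n_frames,
                            stim$shape, geom), "non-empty")
  # identical cohorts in both roles -> constant 0.5 everywhere
  same <- recs
  for (i in seq_along(same)) same[[i]]$group <- c("TD", "ASD")[i %% 2 + 1]
  mirror <- same
  for (i in seq_along(mirror))
    mirror[[i]]$group <- setdiff(c("TD", "ASD"), same[[i]]$group)
  dof_same <- dof_sequence(c(same, mirror), "TD", "ASD", stim$n_frames,
                           stim$shape, geom, map_shape = c(7, 7))
  for (d in dof_same)
    expect_equal(d$grid, matrix(0.5, 7, 7), tolerance = 1e-12)
})
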