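test_that("cardiac phase is linear within a cycle and wraps at peaks", {
  expect_equal(cardiac_phase(c(0, 1, 2), 0.5), pi)
  expect_equal(cardiac_phase(c(0, 1, 2), 1.0), 0)
  expect_equal(cardiac_phase(c(0, 2), 0.5), pi / 2)
  # extrapolation uses the nearest interval
  expect_equal(cardiac_phase(c(1, 2, 4), 0.5), pi)       # before first peak
  expect_equal(cardiac_phase(c(0, 1, 2), 2.25), pi / 2)  # after last peak
  ph <- cardiac_phase(c(0, 0.9, 2, 3.2), seq(0, 3.2, by = 0.05))
  expect_true(all(ph >= 0 & ph < 2 * pi))
  expect_error(cardiac_phase(1, 0.5), "two cardiac peaks")
})

test_that("respiratory phase follows histogram-equalized amplitude with slope sign", {
  t <- seq(0, 20, by = 0.02)
  amp <- sin(2 * pi * 0.25 * t)
  ph <- respiratory_phase(amp, times = t)
  # at the amplitude maximum the phase magnitude approaches pi
  expect_gt(abs(ph[which.max(amp)]), 0.95 * pi)
  # at the median amplitude with positive slope the phase is ~ +pi/2
  rising_mid <- which(abs(amp - stats::median(amp)) < 0.02 &
                        c(diff(amp) > 0, FALSE))[2]
  expect_equal(ph[rising_mid], pi / 2, tolerance = 0.1)
  expect_true(all(ph > -pi & ph <= pi))
  expect_error(respiratory_phase(rep(1, 50)), "constant")
})

test_that("retroicor design column count follows 2c + 2r + 4i^2", {
  set.seed(1)
  cp <- stats::runif(60, 0, 2 * pi)
  rp <- stats::runif(60, 0, 2 * pi)
  for (c_ord in 0:4) for (r_ord in 0:4) for (i_ord in 0:2) {
    d <- retroicor_design(cp, rp, c_ord, r_ord, i_ord)
    expect_equal(ncol(d), 2 * c_ord + 2 * r_ord + 4 * i_ord^2)
  }
  expect_identical(ncol(retroicor_design(cp, rp, 4, 4, 2)), 32L)
  d1 <- retroicor_design(cp, rp, 1, 0, 0)
  expect_identical(colnames(d1), c("card_sin1", "card_cos1"))
  expect_equal(d1[, 1], sin(cp))
  expect_error(retroicor_design(cp, rp[-1]), "same length")
})

test_that("zero respiratory phase degenerates to flagged zero/one columns", {
  cp <- stats::runif(40, 0, 2 * pi)
  expect_warning(d <- retroicor_design(cp, rep(0, 40), 4, 4, 2), "all-zero")
  resp_sin <- grepl("^resp_sin", colnames(d))
  resp_cos <- grepl("^resp_cos", colnames(d))
  expect_true(all(d[, resp_sin] == 0))
  expect_true(all(d[, resp_cos] == 1))
})

test_that("csf regressor averages the most variable voxels", {
  set.seed(2)
  T <- 50
  base <- matrix(stats::rnorm(9 * T, sd = 1), 9, T)
  hot <- stats::rnorm(T, sd = 10)
  blk <- voxel_block(rbind(base, hot), TR = 2)
  expect_equal(csf_regressor(blk, 0.10), hot)
  expect_equal(csf_regressor(blk, 1.0), colMeans(rbind(base, hot)))
  # brute-force variance ranking on 20 iid voxels
  m <- matrix(stats::rnorm(20 * T), 20, T)
  vars <- numeric(20)
  for (i in 1:20) vars[i] <- sum((m[i, ] - mean(m[i, ]))^2) / (T - 1)
  top2 <- sort(order(vars, decreasing = TRUE)[1:2])
  expect_equal(csf_regressor(voxel_block(m, TR = 2), 0.10),
               colMeans(m[top2, , drop = FALSE]))
})

test_that("clean_timeseries with a fully open band just removes the mean", {
  set.seed(3)
  x <- matrix(stats::rnorm(5 * 100), 5, 100)
  TR <- 2
  out <- clean_timeseries(x, band = c(0, 1 / (2 * TR)), TR = TR)
  expect_equal(out, x - rowMeans(x), tolerance = 1e-12)
})

test_that("stop-band content is attenuated by more than 30 dB at its frequency", {
  TR <- 2.08; T <- 288
  t <- (seq_len(T) - 1) * TR
  x <- matrix(sin(2 * pi * 0.2 * t + 0.7), 1, T)
  out <- clean_timeseries(x, band = c(0.01, 0.13), TR = TR)
  # residual power at the tone frequency (matched filter at 0.2 Hz);
  # the total residual also contains the tone's finite-window leakage into
  # the retained pass band, which an exact projection keeps by construction
  B <- cbind(sin(2 * pi * 0.2 * t), cos(2 * pi * 0.2 * t))
  at_freq <- sum(qr.fitted(qr(B), as.numeric(out))^2) / sum(x^2)
  expect_lt(at_freq, 1e-3)
  expect_lt(sum(out^2) / sum(x^2), 5e-3)
})

test_that("cleaning is an idempotent projection with residuals orthogonal to confounds", {
  set.seed(4)
  TR <- 2; T <- 120
  conf <- cbind(stats::rnorm(T), stats::rnorm(T),
                sin(2 * pi * 0.2 * (1:T) * TR))
  conf <- cbind(conf, conf[, 1])  # rank-deficient on purpose
  x <- matrix(stats::rnorm(6 * T), 6, T)
  out <- clean_timeseries(x, confounds = conf, band = c(0.01, 0.13), TR = TR)
  expect_lt(max(abs(out %*% conf)), 1e-8)
  out2 <- clean_timeseries(out, confounds = conf, band = c(0.01, 0.13), TR = TR)
  expect_equal(out2, out, tolerance = 1e-10)
  # over-complete basis is refused
  expect_error(
    clean_timeseries(x[, 1:10, drop = FALSE],
                     confounds = matrix(stats::rnorm(10 * 9), 10, 9),
                     band = c(0.01, 0.13), TR = TR),
    "over-complete")
})

test_that("tsnr is temporal mean over sample standard deviation", {
  z <- stats::rnorm(40)
  z <- (z - mean(z)) / stats::sd(z)            # exactly mean 0, sd 1
  blk <- voxel_block(rbind(100 + 5 * z, z, rep(7, 40)), TR = 2)
  out <- tsnr(blk)
  expect_equal(out[1], 20, ignore_attr = TRUE)
  expect_equal(out[2], 0, ignore_attr = TRUE)
  expect_identical(out[[3]], Inf)
})

test_that("robust parcel mean trims cross-voxel outliers per time point", {
  scheme <- parcellation_scheme(
    data.frame(name = c("a", "b"), structure = "GM", side = "",
               code = "ctx", level = "", network = "X"),
    kind = "brain")
  T <- 10
  # region a: 21 voxels, one corrupted at t = 4; region b: single voxel
  a_rows <- matrix(1.0, 21, T)
  a_rows[21, 4] <- 1e6
  b_row <- matrix(seq_len(T), 1, T)
  blk <- voxel_block(rbind(a_rows, b_row),
                     labels = c(rep("a", 21), "b"), TR = 2)
  ts <- robust_parcel_mean(blk, scheme)
  expect_equal(unclass(ts)["a", ], rep(1.0, T), ignore_attr = TRUE)
  expect_equal(unclass(ts)["b", ], as.numeric(b_row), ignore_attr = TRUE)
  # missing region reported by name
  scheme3 <- parcellation_scheme(
    data.frame(name = c("a", "b", "zz"), structure = "GM", side = "",
               code = "ctx", level = "", network = "X"), kind = "brain")
  expect_error(robust_parcel_mean(blk, scheme3), "zz")
})

test_that("robust parcel mean stays within per-time-point voxel bounds", {
  set.seed(5)
  scheme <- build_spinal_scheme("C4")
  blk <- generate_voxel_block(scheme, n_timepoints = 30,
                              voxels_per_region = 7, noise_sd = 0.5,
                              outlier_fraction = 0.05, seed = 11)
  ts <- unclass(robust_parcel_mean(blk, scheme))
  for (i in seq_len(scheme$n_regions)) {
    rows <- blk$data[blk$labels == scheme$labels$name[i], , drop = FALSE]
    expect_true(all(ts[i, ] >= apply(rows, 2, min) - 1e-12))
    expect_true(all(ts[i, ] <= apply(rows, 2, max) + 1e-12))
  }
})
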