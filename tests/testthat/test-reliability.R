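test_that("identical runs with between-subject spread give ICC 1; no spread gives NaN", {
  set.seed(12)
  run <- matrix(stats::rnorm(10 * 6), 10, 6)   # 10 edges x 6 subjects
  map <- edge_icc(run, run)
  expect_true(all(map[upper.tri(map)] == 1))
  flat <- matrix(0.3, 10, 6)
  map0 <- edge_icc(flat, flat)
  expect_true(all(is.nan(map0[upper.tri(map0)])))
})

test_that("edge ICC matches the one-way ANOVA decomposition from stats::aov", {
  set.seed(13)
  ns <- 6
  run1 <- matrix(stats::rnorm(3 * ns), 3, ns)
  run2 <- matrix(stats::rnorm(3 * ns), 3, ns)
  map <- edge_icc(run1, run2)
  v <- vectorize_upper(map)
  for (e in 1:3) {
    df <- data.frame(y = c(run1[e, ], run2[e, ]),
                     subject = factor(rep(seq_len(ns), 2)))
    ms <- summary(stats::aov(y ~ subject, data = df))[[1]][["Mean Sq"]]
    icc_ref <- (ms[1] - ms[2]) / (ms[1] + ms[2])
    expect_equal(as.numeric(v[e]), icc_ref, tolerance = 1e-10)
  }
})

test_that("edge ICC is symmetric in runs and affine-invariant", {
  set.seed(14)
  run1 <- matrix(stats::rnorm(6 * 5), 6, 5)
  run2 <- matrix(stats::rnorm(6 * 5), 6, 5)
  expect_equal(as.matrix(edge_icc(run1, run2)),
               as.matrix(edge_icc(run2, run1)), tolerance = 1e-12)
  expect_equal(as.matrix(edge_icc(3 * run1 - 1, 3 * run2 - 1)),
               as.matrix(edge_icc(run1, run2)), tolerance = 1e-10)
})

test_that("percentile thresholding matches an exhaustive sort", {
  set.seed(15)
  # 105 edges (N = 15) with distinct values
  vals <- sample(seq(0.001, 0.999, length.out = 105))
  map <- structure(devectorize(vals, n_regions = 15, diag_value = NA_real_),
                   class = c("icc_map", "matrix", "array"), k = 2)
  out <- threshold_percentile(map, 0.95)
  sorted <- sort(vals)
  # type-7 quantile between order statistics
  h <- 1 + (length(vals) - 1) * 0.95
  ref <- sorted[floor(h)] + (h - floor(h)) * (sorted[floor(h) + 1] - sorted[floor(h)])
  expect_equal(out$threshold, ref, tolerance = 1e-12)
  kept <- sum(out$filtered[upper.tri(out$filtered)] > 0)
  expect_equal(kept, sum(vals >= ref))
  expect_true(kept %in% c(5L, 6L))
  # q = 0 keeps everything; constant maps threshold at the constant
  out0 <- threshold_percentile(map, 0)
  expect_equal(as.numeric(vectorize_upper(as.matrix(out0$filtered))), vals)
  cmap <- structure(devectorize(rep(0.4, 105), n_regions = 15,
                                diag_value = NA_real_),
                    class = c("icc_map", "matrix", "array"), k = 2)
  outc <- threshold_percentile(cmap, 0.95)
  expect_equal(outc$threshold, 0.4)
  expect_true(all(outc$filtered[upper.tri(outc$filtered)] == 0.4))
})

test_that("nodal strength aggregates rows in sum and mean modes", {
  m <- matrix(0, 4, 4)
  diag(m) <- NA_real_
  m[1, 2] <- m[2, 1] <- 0.6
  expect_equal(unname(nodal_strength(m)), c(0.6, 0.6, 0, 0))
  cmap <- matrix(0.5, 5, 5); diag(cmap) <- NA_real_
  expect_equal(unname(nodal_strength(cmap, "sum")), rep(4 * 0.5, 5))
  expect_equal(unname(nodal_strength(cmap, "mean")), rep(0.5, 5))
  set.seed(16)
  r <- random_symmetric(7); diag(r) <- NA_real_
  ref <- numeric(7)
  for (i in 1:7) ref[i] <- sum(r[i, -i])
  expect_equal(unname(nodal_strength(r, "sum")), ref, tolerance = 1e-12)
})

test_that("within-level blocks average across levels and maps, NaN-aware", {
  scheme3 <- build_spinal_scheme(c("C4", "C5", "C6"))
  B <- random_symmetric(14, seed = 17); diag(B) <- NA_real_
  rep_block <- function(block, n_levels) {
    n <- 14 * n_levels
    m <- matrix(0.2, n, n); diag(m) <- NA_real_
    for (l in seq_len(n_levels)) {
      idx <- (l - 1) * 14 + 1:14
      m[idx, idx] <- block
    }
    structure(m, class = c("icc_map", "matrix", "array"),
              scheme = build_spinal_scheme(paste0("C", 3 + seq_len(n_levels))),
              k = 2)
  }
  one <- average_within_level_blocks(rep_block(B, 3))
  expect_equal(as.matrix(one)[upper.tri(one)], B[upper.tri(B)],
               tolerance = 1e-12)
  B2 <- random_symmetric(14, seed = 18); diag(B2) <- NA_real_
  two <- average_within_level_blocks(list(rep_block(B, 3), rep_block(B2, 2)))
  ref <- (3 * B + 2 * B2) / 5
  expect_equal(as.matrix(two)[upper.tri(two)], ref[upper.tri(ref)],
               tolerance = 1e-12)
  # a NaN cell in one level averages over the remaining blocks only
  Bn <- B; Bn[1, 2] <- Bn[2, 1] <- NaN
  mixed <- average_within_level_blocks(list(rep_block(B, 1), rep_block(Bn, 1)))
  expect_equal(mixed[1, 2], B[1, 2], tolerance = 1e-12)
  expect_equal(mixed[1, 3], B[1, 3], tolerance = 1e-12)
  expect_error(average_within_level_blocks(list(structure(
    B, class = c("icc_map", "matrix", "array"), scheme = NULL, k = 2))),
    "spinal")
})

test_that("mean edge ICC grows with the subject-stable component", {
  alphas <- c(0, 0.3, 0.6, 0.9)
  means <- vapply(alphas, function(a) {
    m <- vapply(1:5, function(s) {
      v <- tiny_fc_runs(ns = 8, n = 10, t = 100, alpha = a,
                        gamma = min(0.1, 1 - a), noise = 0.4, seed = 100 + s)
      map <- edge_icc(v$run1, v$run2)
      mean(map[upper.tri(map)], na.rm = TRUE)
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_gt(stats::cor(means, alphas, method = "spearman"), 0.9)
})
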