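test_that("identifiability matrix matches brute-force pairwise Pearson", {
  run1 <- list(c(0.1, 0.5, 0.9, 0.3), c(0.8, 0.2, 0.4, 0.6))
  run2 <- list(c(0.2, 0.4, 0.8, 0.5), c(0.9, 0.1, 0.3, 0.7))
  I <- identifiability_matrix(run1, run2)
  for (i in 1:2) for (j in 1:2)
    expect_equal(I[i, j], oracle_pearson(run1[[i]], run2[[j]]),
                 tolerance = 1e-12)
})

test_that("identical runs give a unit diagonal and subject order is equivariant", {
  set.seed(8)
  run <- matrix(stats::rnorm(40 * 5), 40, 5)
  I <- identifiability_matrix(run, run)
  expect_equal(diag(I), rep(1, 5))
  run2 <- matrix(stats::rnorm(40 * 5), 40, 5)
  I12 <- identifiability_matrix(run, run2)
  p <- c(3, 1, 5, 2, 4)
  Ip <- identifiability_matrix(run[, p], run2[, p])
  expect_equal(Ip, I12[p, p], tolerance = 1e-12)
})

test_that("idiff decomposes into diagonal and off-diagonal means", {
  I <- matrix(c(0.8, 0.3, 0.2, 0.9), 2, 2)  # by column: I[1,1]=.8, I[2,1]=.3
  s <- idiff(I)
  expect_equal(s$Iself, 0.85)
  expect_equal(s$Iothers, 0.25)
  expect_equal(s$Idiff, 0.60)
  expect_equal(idiff(diag(2))$Idiff, 1.0)
  expect_equal(idiff(matrix(0.4, 3, 3))$Idiff, 0)
  expect_error(idiff(matrix(1)), "two subjects")
})

test_that("Cohen's d uses the pooled sample variances", {
  I <- matrix(c(0.8, 0.3, 0.2, 0.9), 2, 2)
  expect_equal(cohens_d(I), 0.6 / sqrt(0.005), tolerance = 1e-12)
  expect_error(cohens_d(matrix(c(1, 0, 0, 1), 2, 2)), "pooled variance")
})

test_that("success rate ranks the diagonal within each row, ties failing", {
  # diagonal ranks 1st, 2nd, 3rd in rows 1..3
  I <- rbind(c(0.9, 0.1, 0.2),
             c(0.5, 0.4, 0.3),
             c(0.8, 0.7, 0.1))
  expect_equal(success_rate(I, 1)$rate, 100 / 3, tolerance = 1e-9)
  expect_equal(success_rate(I, 2)$rate, 200 / 3, tolerance = 1e-9)
  expect_equal(success_rate(I, 2)$identified, c(1L, 2L))
  # strict diagonal dominance in rows: always 100% at K = 1
  D <- random_symmetric(6, seed = 10) * 0.3
  diag(D) <- 2
  expect_equal(success_rate(D, 1)$rate, 100)
  # a tie with the diagonal counts as a failure
  tie <- rbind(c(0.5, 0.5), c(0.1, 0.6))
  expect_equal(success_rate(tie, 1)$identified, 2L)
})

test_that("top-K accuracy is non-decreasing in K and rank-invariant", {
  set.seed(11)
  for (rep in 1:20) {
    I <- matrix(stats::runif(64), 8, 8)
    acc <- vapply(1:7, function(k) success_rate(I, k)$rate, numeric(1))
    expect_true(all(diff(acc) >= 0))
    # any strictly increasing transform preserves the rates
    J <- exp(3 * I) - 0.5
    accJ <- vapply(1:7, function(k) success_rate(J, k)$rate, numeric(1))
    expect_equal(accJ, acc)
  }
})

test_that("chance level is 100/Ns", {
  expect_equal(round(chance_level(18), 1), 5.6)
  expect_equal(round(chance_level(43), 1), 2.3)
  expect_equal(chance_level(1), 100)
})

test_that("fingerprint_analysis bundles consistent metrics", {
  v <- tiny_fc_runs(ns = 6, seed = 21)
  fp <- fingerprint_analysis(v$run1, v$run2)
  expect_equal(fp$Idiff, fp$Iself - fp$Iothers)
  expect_equal(unname(fp$accuracy_topk["1"]),
               success_rate(fp$I, 1)$rate)
  expect_equal(fp$cohens_d, cohens_d(fp$I))
  expect_true(all(diff(fp$accuracy_topk) >= 0))
})

test_that("PCA reconstruction at m = 2*Ns recovers the raw Idiff", {
  for (seed in c(31, 32)) {
    v <- tiny_fc_runs(ns = 5, seed = seed)
    raw <- idiff(identifiability_matrix(v$run1, v$run2))$Idiff
    sweep <- pca_differential_identifiability(v$run1, v$run2)
    expect_equal(unname(sweep$idiff_by_components[["10"]]), raw,
                 tolerance = 1e-8)
    expect_gte(sweep$idiff_star, raw - 1e-12)
  }
})

test_that("with a dominant group component the first PC carries no fingerprint", {
  v <- tiny_fc_runs(ns = 6, n = 16, t = 150, alpha = 0.08, gamma = 0.05,
                    noise = 0.2, seed = 41)
  sweep <- pca_differential_identifiability(v$run1, v$run2, m_values = 1)
  expect_lt(abs(sweep$idiff_by_components[["1"]]), 0.05)
  expect_error(pca_differential_identifiability(v$run1, v$run2,
                                                m_values = 40),
               "1..2\\*Ns")
})
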