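# shared fixture builders (all generated in code, seeded per use)

# small two-run FC-vector pair with a controllable subject effect
tiny_fc_runs <- function(ns = 6, n = 12, t = 80, alpha = 0.5, gamma = 0.2,
                         noise = 0.3, seed = 1) {
  spec <- cohort_spec(n_subjects = ns, n_regions = n, n_timepoints = t,
                      alpha = alpha, gamma = gamma, noise_sd = noise,
                      latent_rank = 4, seed = seed)
  cohort_fc_vectors(generate_cohort(spec))
}

# random symmetric matrix with unit diagonal
random_symmetric <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# independent Pearson correlation via the raw-moment formula (oracle path,
# deliberately different from stats::cor)
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# identifiability matrix with exactly `n_hit` diagonal-maximal rows
fixture_identifiability <- function(ns, n_hit, seed = 99) {
  set.seed(seed)
  I <- matrix(stats::runif(ns * ns, 0, 0.5), ns, ns)
  hits <- seq_len(n_hit)
  for (i in seq_len(ns)) {
    if (i %in% hits) {
      I[i, i] <- 0.9                      # strictly above every off-diagonal
    } else {
      I[i, i] <- 0.1
      j <- if (i == 1) 2 else 1
      I[i, j] <- 0.95                     # guarantees a failing row
    }
  }
  I
}
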