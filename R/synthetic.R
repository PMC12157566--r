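#' Specification of a synthetic two-run cohort
#'
#' Fixes the statistical structure of a simulated test-retest cohort: each
#' subject-run correlation target is the convex mixture
#' `(1 - alpha - gamma) * C_group + alpha * C_subj(i) + gamma * C_run(i,r)`
#' of a shared group component, a subject-stable component (the
#' fingerprint) and a run-specific component, each drawn as a random
#' low-rank correlation matrix. Region time series are sampled from a
#' zero-mean multivariate normal with that covariance, plus iid
#' observation noise.
#'
#' Defaults mirror a simultaneous brain+spine style cohort: 15 subjects,
#' 98 regions, 230 volumes at TR 1.55 s, a moderate subject effect
#' (`alpha = 0.3`), a smaller run effect (`gamma = 0.2`) and observation
#' noise of half the signal scale.
#'
#' @param n_subjects,n_regions,n_timepoints cohort dimensions.
#' @param TR sampling interval (s).
#' @param alpha subject-effect weight in `[0, 1]`.
#' @param gamma run-effect weight in `[0, 1 - alpha]`.
#' @param latent_rank rank q of the random-structure construction.
#' @param noise_sd iid observation noise standard deviation (signal series
#'   have unit marginal variance).
#' @param seed integer seed; the cohort is bit-for-bit reproducible from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 15L, n_regions = 98L,
                        n_timepoints = 230L, TR = 1.55,
                        alpha = 0.3, gamma = 0.2, latent_rank = 8L,
                        noise_sd = 0.5, seed = 1L) {
  if (alpha < 0 || gamma < 0 || alpha + gamma > 1)
    stop("need alpha >= 0, gamma >= 0 and alpha + gamma <= 1")
  if (n_subjects < 1L || n_regions < 2L || n_timepoints < 3L)
    stop("cohort dimensions must be positive (and T >= 3)")
  if (latent_rank < 1L) stop("latent_rank must be >= 1")
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_regions = as.integer(n_regions),
         n_timepoints = as.integer(n_timepoints), TR = TR,
         alpha = alpha, gamma = gamma,
         latent_rank = as.integer(latent_rank),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Random low-rank-plus-ridge correlation matrix
#'
#' Draws `W` as an `N x q` standard normal matrix and normalizes
#' `W %*% t(W) + delta * I` to unit diagonal. The result is symmetric
#' positive definite with exactly unit diagonal; small q gives strong,
#' structured correlations, large q concentrates off-diagonals near 0.
#'
#' @param N dimension.
#' @param q latent rank.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param delta diagonal ridge, default `0.05 * q`.
#' @return `N x N` correlation matrix.
#' @export
random_correlation <- function(N, q, seed = NULL, delta = 0.05 * q) {
  if (q < 1L) stop("q must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(stats::rnorm(N * q), N, q)
  S <- tcrossprod(W) + diag(delta, N)
  stats::cov2cor(S)
}

# project a symmetric matrix to the nearest correlation-like PD matrix by
# eigenvalue clipping, then re-normalize to unit diagonal
.nearest_pd_corr <- function(S, floor = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  d <- pmax(e$values, floor)
  S2 <- e$vectors %*% (d * t(e$vectors))
  stats::cov2cor((S2 + t(S2)) / 2)
}

# Cholesky factor, falling back to the PD projection only when needed
# (convex mixtures of PD correlation matrices are already PD)
.chol_pd <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(.nearest_pd_corr(S))
  ch
}

#' Generate a synthetic two-run cohort
#'
#' Materializes the cohort described by a [cohort_spec()]: per subject and
#' run, T samples of an `n_regions`-dimensional zero-mean multivariate
#' normal whose correlation is the group/subject/run mixture, plus iid
#' observation noise. All component matrices are drawn through
#' [random_correlation()] with seeds derived deterministically from
#' `spec$seed`, so the cohort is fully reproducible.
#'
#' @param spec a `cohort_spec`.
#' @param scheme optional `parcellation_scheme` with
#'   `n_regions == spec$n_regions` attached to every run.
#' @return A `synthetic_cohort`: list with `series` (list of subjects,
#'   each a list of two `run_timeseries`), `true_subject_fc` (per-subject
#'   run-independent correlation target), `group_fc`, `spec` and `seeds`
#'   (all derived seeds).
#' @export
generate_cohort <- function(spec, scheme = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(scheme) && scheme$n_regions != spec$n_regions)
    stop("scheme size does not match spec$n_regions")
  ns <- spec$n_subjects
  set.seed(spec$seed)
  n_seeds <- 1L + ns + 2L * ns + 2L * ns  # group, subj, run-structure, noise
  seeds <- sample.int(.Machine$integer.max, n_seeds)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }
  N <- spec$n_regions; T <- spec$n_timepoints
  w_group <- 1 - spec$alpha - spec$gamma
  C_group <- random_correlation(N, spec$latent_rank, seed = next_seed())
  series <- vector("list", ns)
  true_fc <- vector("list", ns)
  for (i in seq_len(ns)) {
    C_subj <- random_correlation(N, spec$latent_rank, seed = next_seed())
    base <- w_group * C_group + spec$alpha * C_subj
    true_fc[[i]] <- stats::cov2cor(base + diag(spec$gamma, N))
    runs <- vector("list", 2L)
    for (r in 1:2) {
      C_run <- random_correlation(N, spec$latent_rank, seed = next_seed())
      Sigma <- base + spec$gamma * C_run
      L <- .chol_pd(Sigma)
      set.seed(next_seed())
      Z <- matrix(stats::rnorm(N * T), N, T)
      x <- crossprod(L, Z)
      if (spec$noise_sd > 0)
        x <- x + spec$noise_sd * matrix(stats::rnorm(N * T), N, T)
      runs[[r]] <- run_timeseries(
        x, TR = spec$TR, scheme = scheme,
        subject_id = sprintf("sub-%02d", i), run_id = sprintf("run-%d", r))
    }
    series[[i]] <- runs
  }
  structure(
    list(series = series, true_subject_fc = true_fc, group_fc = C_group,
         spec = spec, seeds = seeds),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "synthetic_cohort: %d subjects x 2 runs, %d regions x %d time points\n",
    s$n_subjects, s$n_regions, s$n_timepoints))
  cat(sprintf("  alpha = %g, gamma = %g, noise_sd = %g, seed = %d\n",
              s$alpha, s$gamma, s$noise_sd, s$seed))
  invisible(x)
}

#' FC vectors per run for a cohort
#'
#' Convenience: computes the FC matrix of every subject-run and returns the
#' two runs as `M x Ns` matrices of upper-triangle vectors, ready for
#' [fingerprint_analysis()] or [edge_icc()].
#'
#' @param cohort a `synthetic_cohort` (or list of per-subject two-run
#'   lists of `run_timeseries`).
#' @return list with elements `run1` and `run2`.
#' @export
cohort_fc_vectors <- function(cohort) {
  series <- if (inherits(cohort, "synthetic_cohort")) cohort$series else cohort
  vecs <- lapply(1:2, function(r) {
    do.call(cbind, lapply(series, function(subj) .vec_upper(compute_fc(subj[[r]]))))
  })
  names(vecs) <- c("run1", "run2")
  vecs
}

#' Generate a causally driven brain/spine cohort pair
#'
#' Builds a predictor cohort X as in [generate_cohort()] and a target
#' cohort Y driven by it: `Y(i, r) = A_i %*% X(i, r) + noise`, with `A_i` a
#' sparse subject-specific mixing matrix fixed across the two runs. All of
#' Y's identifiable structure is inherited from X (plus the mixing), which
#' makes the pair the ground-truth testbed for cross-regression residual
#' fingerprinting: regressing X out of Y should destroy Y's fingerprint,
#' regressing Y out of X should leave X's largely intact.
#'
#' @param spec a `cohort_spec` for the predictor cohort X.
#' @param n_target number of target (Y) regions.
#' @param mixing_density fraction of non-zero entries in each `A_i`,
#'   in `(0, 1]` (0 is allowed and yields pure-noise targets).
#' @param target_noise_sd iid noise added to Y.
#' @return list with `x`, `y` (lists of per-subject two-run
#'   `run_timeseries` lists), `mixing` (list of `A_i`), and `spec`.
#' @export
generate_driven_pair <- function(spec, n_target, mixing_density = 0.3,
                                 target_noise_sd = 0.5) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (mixing_density < 0 || mixing_density > 1)
    stop("mixing_density must be in [0, 1]")
  xc <- generate_cohort(spec)
  ns <- spec$n_subjects
  set.seed(spec$seed + 1L)
  mix_seeds <- sample.int(.Machine$integer.max, ns + 2L * ns)
  N <- spec$n_regions; T <- spec$n_timepoints
  scale <- if (mixing_density > 0) 1 / sqrt(mixing_density * N) else 0
  y <- vector("list", ns)
  mixing <- vector("list", ns)
  for (i in seq_len(ns)) {
    set.seed(mix_seeds[i])
    A <- matrix(stats::rnorm(n_target * N), n_target, N) *
      matrix(stats::rbinom(n_target * N, 1, mixing_density), n_target, N) *
      scale
    mixing[[i]] <- A
    runs <- vector("list", 2L)
    for (r in 1:2) {
      set.seed(mix_seeds[ns + 2L * (i - 1L) + r])
      noise <- target_noise_sd * matrix(stats::rnorm(n_target * T), n_target, T)
      runs[[r]] <- run_timeseries(
        A %*% unclass(xc$series[[i]][[r]]) + noise, TR = spec$TR,
        subject_id = sprintf("sub-%02d", i), run_id = sprintf("run-%d", r))
    }
    y[[i]] <- runs
  }
  list(x = xc$series, y = y, mixing = mixing, spec = spec)
}

#' Synthetic physiological traces
#'
#' Cardiac peak times at jittered multiples of the heart period and a
#' respiratory waveform (noisy sinusoid), suitable inputs for
#' [cardiac_phase()], [respiratory_phase()] and [retroicor_design()].
#'
#' @param duration_s trace duration (s).
#' @param heart_rate_hz mean heart rate (Hz), default 1.1.
#' @param resp_rate_hz respiration rate (Hz), default 0.25.
#' @param jitter_sd cardiac peak-time jitter standard deviation (s).
#' @param seed optional integer seed.
#' @param resp_fs respiratory waveform sampling rate (Hz), default 10.
#' @param resp_noise_sd amplitude noise on the waveform, default 0.05.
#' @return list with `cardiac_peaks` (numeric, s) and `resp` (list:
#'   `time`, `amplitude`).
#' @export
generate_physio <- function(duration_s, heart_rate_hz = 1.1,
                            resp_rate_hz = 0.25, jitter_sd = 0.02,
                            seed = NULL, resp_fs = 10,
                            resp_noise_sd = 0.05) {
  if (heart_rate_hz <= 0 || resp_rate_hz <= 0) stop("rates must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_beats <- floor(duration_s * heart_rate_hz)
  peaks <- (0:n_beats) / heart_rate_hz
  if (jitter_sd > 0) {
    peaks <- peaks + stats::rnorm(length(peaks), sd = jitter_sd)
    peaks <- sort(peaks)
    # enforce strict monotonicity (jitter can reorder at extreme draws)
    peaks <- peaks + seq_along(peaks) * 1e-9
  }
  t_resp <- seq(0, duration_s, by = 1 / resp_fs)
  amp <- sin(2 * pi * resp_rate_hz * t_resp)
  if (resp_noise_sd > 0)
    amp <- amp + stats::rnorm(length(amp), sd = resp_noise_sd)
  list(cardiac_peaks = peaks, resp = list(time = t_resp, amplitude = amp))
}

#' Synthetic voxel block with optional outliers
#'
#' Each region of the scheme gets `voxels_per_region` voxels sharing that
#' region's ground-truth series plus iid noise; a stated fraction of
#' voxel-time entries is replaced by large-magnitude outliers. Feeds
#' [robust_parcel_mean()] and [tsnr()].
#'
#' @param scheme a `parcellation_scheme`.
#' @param n_timepoints T.
#' @param voxels_per_region voxels per region, `>= 1`.
#' @param noise_sd per-voxel noise standard deviation.
#' @param outlier_fraction fraction of voxel-time entries replaced.
#' @param outlier_scale magnitude of the outliers (sign random).
#' @param TR sampling interval (s).
#' @param seed optional integer seed.
#' @return a `voxel_block` with the ground-truth region series attached as
#'   attribute `truth` (regions x T).
#' @export
generate_voxel_block <- function(scheme, n_timepoints,
                                 voxels_per_region = 10L, noise_sd = 0.1,
                                 outlier_fraction = 0, outlier_scale = 100,
                                 TR = 2, seed = NULL) {
  stopifnot(inherits(scheme, "parcellation_scheme"))
  if (voxels_per_region < 1L) stop("voxels_per_region must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  N <- scheme$n_regions; T <- as.integer(n_timepoints)
  truth <- matrix(stats::rnorm(N * T), N, T,
                  dimnames = list(scheme$labels$name, NULL))
  V <- N * voxels_per_region
  data <- truth[rep(seq_len(N), each = voxels_per_region), , drop = FALSE] +
    matrix(stats::rnorm(V * T, sd = noise_sd), V, T)
  labels <- rep(scheme$labels$name, each = voxels_per_region)
  if (outlier_fraction > 0) {
    n_out <- round(outlier_fraction * length(data))
    idx <- sample.int(length(data), n_out)
    data[idx] <- outlier_scale * sample(c(-1, 1), n_out, replace = TRUE)
  }
  block <- voxel_block(data, labels = labels, TR = TR)
  attr(block, "truth") <- truth
  block
}
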