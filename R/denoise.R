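#' Voxel-level time-series block
#'
#' A small container for voxel (or channel) time series prior to
#' parcellation: a V x T matrix, an optional per-voxel region label, and the
#' sampling interval.
#'
#' @param data numeric matrix, voxels x time points.
#' @param labels character vector of per-voxel region names (may be `""`,
#'   e.g. for CSF blocks); recycled if length 1.
#' @param TR sampling interval in seconds.
#' @return An object of class `voxel_block`.
#' @export
voxel_block <- function(data, labels = "", TR = 1) {
  data <- as.matrix(data)
  if (nrow(data) < 1L) stop("voxel block needs at least one voxel")
  if (ncol(data) < 2L) stop("voxel block needs at least two time points")
  labels <- rep_len(as.character(labels), nrow(data))
  structure(list(data = data, labels = labels, TR = as.numeric(TR)),
            class = "voxel_block")
}

#' @export
print.voxel_block <- function(x, ...) {
  cat(sprintf("voxel_block: %d voxels x %d time points, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$TR))
  invisible(x)
}

#' Cardiac phase from peak times
#'
#' Assigns each acquisition time a cardiac phase in `[0, 2*pi)`: within the
#' cycle `[t_k, t_{k+1})` the phase grows linearly from 0 at the peak to
#' `2*pi` at the next peak. Samples before the first peak or after the last
#' use the nearest inter-peak interval, extrapolated.
#'
#' @param peak_times increasing numeric vector of cardiac peak times (s);
#'   at least two peaks.
#' @param sample_times numeric vector of times (s) at which the phase is
#'   evaluated (typically volume acquisition times).
#' @return numeric vector of phases in `[0, 2*pi)`, one per sample time.
#' @export
cardiac_phase <- function(peak_times, sample_times) {
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) < 2L)
    stop("at least two cardiac peaks are required")
  if (is.unsorted(peak_times, strictly = TRUE))
    stop("peak_times must be strictly increasing")
  n <- length(peak_times)
  k <- findInterval(sample_times, peak_times)
  # clamp to the nearest existing interval for extrapolation
  k <- pmin(pmax(k, 1L), n - 1L)
  frac <- (sample_times - peak_times[k]) / (peak_times[k + 1L] - peak_times[k])
  (2 * pi * frac) %% (2 * pi)
}

#' Respiratory phase by histogram equalization
#'
#' Computes a respiration phase in `(-pi, pi]` in the style of Glover's
#' RETROICOR: the magnitude is the empirical percentile of the respiratory
#' amplitude times `pi` (histogram equalization over the whole trace), and
#' the sign is that of the smoothed derivative of the waveform (positive
#' while inhaling/rising).
#'
#' @param amplitude numeric respiratory waveform.
#' @param times times (s) of the waveform samples; defaults to a unit grid.
#' @param sample_times times (s) at which the phase is required; defaults to
#'   `times`. Amplitude and slope are interpolated linearly to these times
#'   before the phase is formed (interpolating the wrapped phase itself
#'   would corrupt values near the `+/-pi` seam).
#' @param smooth_k width (samples) of the moving-average smoothing of the
#'   derivative; default 3.
#' @return numeric vector of phases in `(-pi, pi]`.
#' @export
respiratory_phase <- function(amplitude, times = seq_along(amplitude) - 1,
                              sample_times = times, smooth_k = 3L) {
  amplitude <- as.numeric(amplitude)
  if (length(amplitude) < 2L) stop("waveform must have at least two samples")
  if (max(amplitude) == min(amplitude))
    stop("constant respiratory waveform: phase undefined")
  if (length(times) != length(amplitude))
    stop("times and amplitude must have the same length")
  deriv <- c(diff(amplitude) / diff(times), NA)
  deriv[length(deriv)] <- deriv[length(deriv) - 1L]
  if (smooth_k > 1L)
    deriv <- stats::filter(deriv, rep(1 / smooth_k, smooth_k), sides = 2)
  deriv <- as.numeric(deriv)
  # moving-average ends: fall back to the raw derivative
  raw <- c(diff(amplitude) / diff(times), NA)
  raw[length(raw)] <- raw[length(raw) - 1L]
  deriv[is.na(deriv)] <- raw[is.na(deriv)]
  ecdf_fun <- stats::ecdf(amplitude)
  amp_s <- stats::approx(times, amplitude, xout = sample_times, rule = 2)$y
  der_s <- stats::approx(times, deriv, xout = sample_times, rule = 2)$y
  sgn <- ifelse(der_s >= 0, 1, -1)
  phase <- sgn * pi * ecdf_fun(amp_s)
  # map -pi to +pi so the range is (-pi, pi]
  phase[phase <= -pi] <- pi
  phase
}

#' RETROICOR Fourier nuisance design
#'
#' Expands cardiac and respiratory phases into the Fourier regressor set of
#' retrospective physiological noise correction: sine/cosine pairs of the
#' cardiac phase up to `card_order`, of the respiratory phase up to
#' `resp_order`, and of the sum and difference combinations
#' `mc*phi_c +/- mr*phi_r` for `mc, mr = 1..interaction_order`. The column
#' count is `2*card_order + 2*resp_order + 4*interaction_order^2`; the
#' guideline setting (4, 4, 2) yields 32 regressors.
#'
#' @param card_phase cardiac phase per volume (radians).
#' @param resp_phase respiratory phase per volume (radians); same length.
#' @param card_order,resp_order,interaction_order non-negative integers.
#' @return numeric matrix (T x R) with descriptive column names; columns
#'   that are numerically constant at zero trigger a warning (e.g. sine
#'   terms of an identically zero phase).
#' @export
retroicor_design <- function(card_phase, resp_phase,
                             card_order = 4L, resp_order = 4L,
                             interaction_order = 2L) {
  if (length(card_phase) != length(resp_phase))
    stop("cardiac and respiratory phase series must have the same length")
  if (card_order < 0 || resp_order < 0 || interaction_order < 0)
    stop("orders must be non-negative")
  cols <- list()
  add <- function(x, nm) {
    cols[[length(cols) + 1L]] <<- stats::setNames(list(x), nm)
  }
  for (m in seq_len(card_order)) {
    add(sin(m * card_phase), sprintf("card_sin%d", m))
    add(cos(m * card_phase), sprintf("card_cos%d", m))
  }
  for (m in seq_len(resp_order)) {
    add(sin(m * resp_phase), sprintf("resp_sin%d", m))
    add(cos(m * resp_phase), sprintf("resp_cos%d", m))
  }
  for (mc in seq_len(interaction_order)) {
    for (mr in seq_len(interaction_order)) {
      plus <- mc * card_phase + mr * resp_phase
      minus <- mc * card_phase - mr * resp_phase
      add(sin(plus), sprintf("int_sin_c%d+r%d", mc, mr))
      add(cos(plus), sprintf("int_cos_c%d+r%d", mc, mr))
      add(sin(minus), sprintf("int_sin_c%d-r%d", mc, mr))
      add(cos(minus), sprintf("int_cos_c%d-r%d", mc, mr))
    }
  }
  if (!length(cols))
    return(matrix(numeric(0), nrow = length(card_phase), ncol = 0))
  nms <- vapply(cols, names, character(1))
  design <- do.call(cbind, lapply(cols, `[[`, 1L))
  colnames(design) <- nms
  zero <- apply(design, 2, function(x) all(abs(x) < 1e-12))
  if (any(zero))
    warning("all-zero regressor column(s): ",
            paste(nms[zero], collapse = ", "))
  design
}

#' CSF nuisance regressor
#'
#' Averages the most variable cerebrospinal-fluid voxels into a single
#' nuisance time course: voxels are ranked by temporal variance and the top
#' `ceil(fraction * V)` are averaged.
#'
#' @param csf a `voxel_block` of CSF voxel time series.
#' @param fraction fraction of voxels to keep, in (0, 1]; default 0.10.
#' @return numeric vector of length T.
#' @export
csf_regressor <- function(csf, fraction = 0.10) {
  stopifnot(inherits(csf, "voxel_block"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  v <- apply(csf$data, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(ceiling(fraction * nrow(csf$data)))]
  colMeans(csf$data[keep, , drop = FALSE])
}

# discrete-cosine basis columns whose frequencies fall OUTSIDE [f_lo, f_hi];
# DCT-II column k (k = 1..T-1) has frequency k / (2 * T * TR) Hz
.dct_stopband <- function(T, TR, band) {
  k <- seq_len(T - 1L)
  f <- k / (2 * T * TR)
  k <- k[f < band[1] | f > band[2]]
  if (!length(k)) return(matrix(numeric(0), nrow = T, ncol = 0))
  t_idx <- seq_len(T) - 0.5
  vapply(k, function(kk) cos(pi * kk * t_idx / T), numeric(T))
}

#' Joint confound and band-pass cleaning by a single projection
#'
#' Removes nuisance confounds and all frequency content outside a pass band
#' in one least-squares projection: a discrete-cosine basis of every
#' frequency outside `[band[1], band[2]]` is concatenated with the confound
#' columns and an intercept, and the joint fit is subtracted. Because both
#' parts live in the same orthogonal complement, the residuals are exactly
#' orthogonal to every confound column, and the operation is idempotent --
#' the behaviour of applying the filter and the confound regression
#' sequentially does not have either property.
#'
#' @param data numeric matrix, channels x T (regions, voxels or slices).
#' @param confounds optional T x R confound matrix (e.g. from
#'   [retroicor_design()] plus a CSF regressor); `NULL` for filtering only.
#' @param band pass-band cut-off frequencies in Hz, default `c(0.01, 0.13)`.
#' @param TR sampling interval in seconds.
#' @return cleaned matrix of the same shape as `data`.
#' @export
clean_timeseries <- function(data, confounds = NULL, band = c(0.01, 0.13),
                             TR) {
  data <- as.matrix(data)
  T <- ncol(data)
  if (T < 3L) stop("need at least 3 time points")
  nyquist <- 1 / (2 * TR)
  if (!(band[1] < band[2]))
    stop("band must satisfy f_lo < f_hi")
  if (band[2] > nyquist + 1e-12)
    stop(sprintf("f_hi (%g Hz) exceeds the Nyquist frequency (%g Hz)",
                 band[2], nyquist))
  nuis <- cbind(intercept = rep(1, T), .dct_stopband(T, TR, band))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != T)
      stop("confound matrix must have one row per time point")
    nuis <- cbind(nuis, confounds)
  }
  if (ncol(nuis) >= T)
    stop("nuisance basis is over-complete (", ncol(nuis), " columns for ",
         T, " time points); shorten the stop band or the confound set")
  # orthonormal basis of the nuisance space via SVD (rank-deficient safe)
  sv <- svd(nuis, nu = min(dim(nuis)), nv = 0)
  r <- sum(sv$d > max(dim(nuis)) * .Machine$double.eps * sv$d[1])
  U <- sv$u[, seq_len(r), drop = FALSE]
  xt <- t(data)
  cleaned <- xt - U %*% crossprod(U, xt)
  out <- t(cleaned)
  dimnames(out) <- dimnames(data)
  out
}

#' Temporal signal-to-noise ratio
#'
#' Each voxel's temporal mean divided by its temporal standard deviation
#' (sample standard deviation, n - 1 denominator). Voxels with zero
#' temporal variance map to `Inf`.
#'
#' @param block a `voxel_block`.
#' @return numeric vector of per-voxel tSNR values.
#' @export
tsnr <- function(block) {
  stopifnot(inherits(block, "voxel_block"))
  m <- rowMeans(block$data)
  s <- apply(block$data, 1, stats::sd)
  out <- ifelse(s == 0, Inf, m / s)
  names(out) <- rownames(block$data)
  out
}

#' Robust (trimmed-mean) parcellation of voxel time series
#'
#' Averages voxels into region time series with a robust mean: at each time
#' point, voxel values of a region below its 5th or above its 95th
#' cross-voxel percentile are excluded before averaging. Regions with fewer
#' than 5 voxels fall back to the plain mean (the trim is vacuous there).
#'
#' @param block a `voxel_block` whose `labels` name the region of each voxel.
#' @param scheme the target `parcellation_scheme`; every region must have at
#'   least one voxel.
#' @param trim lower/upper percentile bounds, default `c(0.05, 0.95)`.
#' @return A [run_timeseries()] of dimension `n_regions x T`.
#' @export
robust_parcel_mean <- function(block, scheme, trim = c(0.05, 0.95)) {
  stopifnot(inherits(block, "voxel_block"),
            inherits(scheme, "parcellation_scheme"))
  missing <- setdiff(scheme$labels$name, block$labels)
  if (length(missing))
    stop("region(s) with zero voxels: ", paste(missing, collapse = ", "))
  T <- ncol(block$data)
  out <- matrix(NA_real_, nrow = scheme$n_regions, ncol = T,
                dimnames = list(scheme$labels$name, NULL))
  for (i in seq_len(scheme$n_regions)) {
    rows <- block$data[block$labels == scheme$labels$name[i], , drop = FALSE]
    if (nrow(rows) < 5L) {
      out[i, ] <- colMeans(rows)
    } else {
      out[i, ] <- vapply(seq_len(T), function(t) {
        x <- rows[, t]
        q <- stats::quantile(x, trim, names = FALSE, type = 7)
        mean(x[x >= q[1] & x <= q[2]])
      }, numeric(1))
    }
  }
  run_timeseries(out, TR = block$TR, scheme = scheme)
}
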