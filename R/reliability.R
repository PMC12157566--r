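#' Edge-wise ICC(1,1) test-retest reliability map
#'
#' For every FC edge, fits the one-way random-effects ANOVA with subjects
#' as groups and the two runs as repeated measurements and computes
#' `ICC(1,1) = (MSR - MSW) / (MSR + (k-1)*MSW)` with `k = 2`, where MSR is
#' the between-subject mean square and MSW the within-subject (error) mean
#' square. The per-edge values are folded back into the symmetric N x N
#' edge space (diagonal `NA`). Edges with zero total variance are `NaN` and
#' excluded from downstream percentiles.
#'
#' @param run1,run2 FC vectors per subject (list or `M x Ns` matrix with
#'   subjects in columns; same subject order). Typically the
#'   [vectorize_upper()] output of per-run FC matrices.
#' @param scheme optional `parcellation_scheme` attached to the map.
#' @return An `icc_map`: symmetric `N x N` matrix with attributes `scheme`
#'   and `k`; `N` is recovered from the edge count.
#' @export
edge_icc <- function(run1, run2, scheme = NULL) {
  a <- as.matrix(if (is.list(run1)) do.call(cbind, run1) else run1)
  b <- as.matrix(if (is.list(run2)) do.call(cbind, run2) else run2)
  if (!identical(dim(a), dim(b))) stop("runs must have identical dimensions")
  ns <- ncol(a)
  if (ns < 2L) stop("at least two subjects are required")
  k <- 2
  subj_mean <- (a + b) / 2                       # M x Ns
  grand <- rowMeans(cbind(a, b))                 # M
  msr <- k * rowSums((subj_mean - grand)^2) / (ns - 1)
  msw <- rowSums((a - subj_mean)^2 + (b - subj_mean)^2) / (ns * (k - 1))
  denom <- msr + (k - 1) * msw
  icc <- ifelse(denom == 0, NaN, (msr - msw) / denom)
  m <- length(icc)
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(n - round(n)) > 1e-9)
    stop("edge count is not of the form N*(N-1)/2")
  values <- devectorize(icc, n_regions = round(n), diag_value = NA_real_)
  if (!is.null(scheme)) {
    if (scheme$n_regions != round(n))
      stop("scheme size does not match the edge count")
    dimnames(values) <- list(scheme$labels$name, scheme$labels$name)
  }
  structure(values, class = c("icc_map", "matrix", "array"),
            scheme = scheme, k = k)
}

#' @export
print.icc_map <- function(x, ...) {
  v <- x[upper.tri(x)]
  cat(sprintf("icc_map: %d regions, %d edges (%d finite), k = %d\n",
              nrow(x), length(v), sum(is.finite(v)), attr(x, "k")))
  if (any(is.finite(v)))
    cat(sprintf("  ICC range: [%.3f, %.3f]\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Percentile thresholding of an ICC map
#'
#' Computes the q-quantile (linear interpolation between order statistics,
#' `stats::quantile` type 7) of the finite upper-triangle edge values --
#' each undirected edge counted once -- and zeroes every edge below it,
#' retaining only the most reliable connections.
#'
#' @param map an `icc_map`.
#' @param q quantile in `[0, 1]`, default 0.95.
#' @return list with `threshold` (numeric) and `filtered` (an `icc_map`
#'   with sub-threshold edges set to 0; `NaN` edges are also zeroed).
#' @export
threshold_percentile <- function(map, q = 0.95) {
  v <- map[upper.tri(map)]
  v <- v[is.finite(v)]
  if (!length(v)) stop("ICC map has no finite edge values")
  thr <- stats::quantile(v, q, names = FALSE, type = 7)
  filtered <- map
  filtered[!is.finite(filtered) | filtered < thr] <- 0
  diag(filtered) <- NA_real_
  attributes(filtered) <- attributes(map)
  list(threshold = thr, filtered = filtered)
}

#' Nodal strength of a (filtered) reliability map
#'
#' Aggregates each region's row of the map into a single reliability score:
#' the sum (default) or the mean of its edge values. `NA`/`NaN` entries
#' (including the diagonal) count as 0 for the sum and are excluded from
#' the mean.
#'
#' @param map an `icc_map` (usually the `filtered` element of
#'   [threshold_percentile()]).
#' @param mode `"sum"` (default) or `"mean"`.
#' @return named numeric vector, one value per region.
#' @export
nodal_strength <- function(map, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  m <- as.matrix(map)
  out <- if (mode == "sum") {
    m0 <- m
    m0[!is.finite(m0)] <- 0
    rowSums(m0)
  } else {
    apply(m, 1, function(x) mean(x[is.finite(x)]))
  }
  names(out) <- rownames(m)
  out
}

#' Average ICC within-level blocks down to the 14-region cross-section
#'
#' Each spinal ICC map is a block matrix over `14 * L` regions (L spinal
#' levels in the canonical cross-section order). This extracts the L
#' within-level 14 x 14 diagonal blocks from every map and averages all
#' blocks elementwise across levels and maps, ignoring `NaN` cells.
#' Between-level edges are not included.
#'
#' @param maps a single `icc_map` or a list of them, all over spinal
#'   schemes in the canonical cross-section order.
#' @return a 14 x 14 `icc_map` labelled with the cross-section region
#'   names (no level tag).
#' @export
average_within_level_blocks <- function(maps) {
  if (inherits(maps, "icc_map")) maps <- list(maps)
  blocks <- list()
  for (map in maps) {
    scheme <- attr(map, "scheme")
    if (is.null(scheme) || scheme$kind != "spinal")
      stop("all maps must carry a spinal parcellation scheme")
    n_levels <- scheme$n_regions / 14L
    for (l in seq_len(n_levels)) {
      idx <- (l - 1L) * 14L + seq_len(14L)
      blocks[[length(blocks) + 1L]] <- as.matrix(map)[idx, idx]
    }
  }
  arr <- simplify2array(blocks)
  avg <- apply(arr, c(1, 2), function(x) {
    x <- x[is.finite(x)]
    if (length(x)) mean(x) else NaN
  })
  diag(avg) <- NA_real_
  cross <- build_spinal_scheme("C1")  # canonical order source
  nms <- sub("^C1_", "", cross$labels$name)
  dimnames(avg) <- list(nms, nms)
  structure(avg, class = c("icc_map", "matrix", "array"),
            scheme = NULL, k = attr(maps[[1]], "k"))
}
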