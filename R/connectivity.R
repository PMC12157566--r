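#' Parcelled run time series
#'
#' One subject-run matrix of region time series: N regions x T time points,
#' with the sampling interval and (optionally) the parcellation scheme that
#' fixes the row order.
#'
#' @param data numeric matrix, regions x time points; row names are region
#'   names (taken from `scheme` when supplied).
#' @param TR sampling interval in seconds.
#' @param scheme optional `parcellation_scheme`; when given, `nrow(data)`
#'   must equal `scheme$n_regions` and rows are labelled from it.
#' @param subject_id,run_id identifier strings.
#' @return An object of class `run_timeseries` (a numeric matrix with
#'   attributes `TR`, `scheme`, `subject_id`, `run_id`).
#' @export
run_timeseries <- function(data, TR, scheme = NULL, subject_id = "",
                           run_id = "") {
  data <- as.matrix(data)
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "parcellation_scheme"))
    if (nrow(data) != scheme$n_regions)
      stop(sprintf("data has %d rows but scheme has %d regions",
                   nrow(data), scheme$n_regions))
    rownames(data) <- scheme$labels$name
  } else if (is.null(rownames(data))) {
    rownames(data) <- sprintf("R%03d", seq_len(nrow(data)))
  }
  structure(data, class = c("run_timeseries", "matrix", "array"),
            TR = as.numeric(TR), scheme = scheme,
            subject_id = as.character(subject_id),
            run_id = as.character(run_id))
}

#' @export
print.run_timeseries <- function(x, ...) {
  cat(sprintf("run_timeseries: %d regions x %d time points, TR = %g s",
              nrow(x), ncol(x), attr(x, "TR")))
  ids <- c(attr(x, "subject_id"), attr(x, "run_id"))
  if (any(nzchar(ids))) cat(sprintf("  [%s / %s]", ids[1], ids[2]))
  cat("\n")
  invisible(x)
}

.constant_rows <- function(data) {
  rng <- apply(data, 1, function(x) diff(range(x)))
  which(rng == 0)
}

#' Functional connectivity matrix
#'
#' Pearson correlation between every pair of region time series; the
#' diagonal is set to exactly 1. Region series must be non-constant.
#'
#' @param ts a `run_timeseries` (or plain regions x time matrix).
#' @return An `fc_matrix`: symmetric N x N correlation matrix with the
#'   scheme (if any) attached.
#' @export
compute_fc <- function(ts) {
  data <- unclass(ts)
  if (ncol(data) < 3L) stop("need at least 3 time points for correlation")
  const <- .constant_rows(data)
  if (length(const))
    stop("constant region time series: ",
         paste(rownames(data)[const], collapse = ", "))
  fc <- stats::cor(t(data))
  diag(fc) <- 1
  structure(fc, class = c("fc_matrix", "matrix", "array"),
            scheme = attr(ts, "scheme"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("fc_matrix: %d x %d\n", nrow(x), ncol(x)))
  invisible(x)
}

# fast internal path: row-major upper-triangle vectorization
.vec_upper <- function(m) t(m)[lower.tri(m)]

#' Vectorize the upper triangle of an FC matrix
#'
#' Unfolds the upper triangular part (excluding the diagonal) of a symmetric
#' N x N matrix into a vector of length `M = N*(N-1)/2` in row-major order
#' over pairs `(i, j)` with `i < j` -- the canonical edge order used by
#' every module (identifiability, ICC maps, PCA).
#'
#' @param fc an `fc_matrix` (or any symmetric numeric matrix).
#' @return numeric vector of length `N*(N-1)/2` with attributes `n_regions`
#'   and `edge_index` (two-column matrix of region indices `i < j`).
#' @export
vectorize_upper <- function(fc) {
  m <- as.matrix(fc)
  n <- nrow(m)
  if (n != ncol(m)) stop("matrix must be square")
  idx <- which(lower.tri(m), arr.ind = TRUE)  # on t(m): (col,row) of m
  v <- .vec_upper(m)
  structure(v, n_regions = n,
            edge_index = cbind(i = idx[, 2L], j = idx[, 1L]),
            region_names = rownames(m))
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' Inverse of [vectorize_upper()]: restores the symmetric `N x N` matrix
#' (diagonal set to `diag_value`).
#'
#' @param v numeric vector of length `N*(N-1)/2`.
#' @param n_regions N; defaults to the attribute stored by
#'   [vectorize_upper()].
#' @param diag_value value for the diagonal, default 1.
#' @return symmetric numeric matrix.
#' @export
devectorize <- function(v, n_regions = attr(v, "n_regions"), diag_value = 1) {
  if (is.null(n_regions)) stop("n_regions is required")
  n <- as.integer(n_regions)
  if (length(v) != n * (n - 1) / 2)
    stop("vector length does not match n_regions*(n_regions-1)/2")
  m <- matrix(0, n, n)
  tm <- t(m)
  tm[lower.tri(tm)] <- as.numeric(v)
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- diag_value
  nms <- attr(v, "region_names")
  if (!is.null(nms)) dimnames(m) <- list(nms, nms)
  m
}

.resolve_regions <- function(fc, which) {
  if (is.character(which)) {
    idx <- match(which, rownames(fc))
    if (anyNA(idx))
      stop("unknown region(s): ", paste(which[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(which)
}

#' Extract and flatten a block of an FC matrix
#'
#' For a square block (`rows` identical to `cols`, e.g. brain-only or
#' spine-only) returns the upper-triangle vector of the sub-matrix; for a
#' rectangular block over two disjoint region sets (e.g. brain x spine)
#' returns the full block flattened row-major. These are the three FC
#' profiles (within-brain, within-spine, brain-spine interaction) fed to
#' the fingerprinting pipeline in full field-of-view analyses.
#'
#' @param fc an `fc_matrix` over a combined scheme.
#' @param rows,cols region names or indices.
#' @return numeric vector (length `k*(k-1)/2` for a square block of size k,
#'   `length(rows)*length(cols)` for a rectangular block).
#' @export
extract_block <- function(fc, rows, cols = rows) {
  ri <- .resolve_regions(fc, rows)
  ci <- .resolve_regions(fc, cols)
  if (identical(sort(ri), sort(ci))) {
    vectorize_upper(as.matrix(fc)[ri, ri, drop = FALSE])
  } else {
    if (length(intersect(ri, ci)))
      stop("rows and cols overlap; rectangular blocks need disjoint sets")
    as.vector(t(as.matrix(fc)[ri, ci, drop = FALSE]))
  }
}
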