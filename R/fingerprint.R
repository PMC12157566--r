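.as_fc_stack <- function(x, what = "run") {
  # accept a list of FC vectors or an M x Ns matrix (columns = subjects)
  if (is.list(x)) x <- do.call(cbind, lapply(x, as.numeric))
  x <- as.matrix(x)
  const <- which(apply(x, 2, function(v) diff(range(v)) == 0))
  if (length(const))
    stop("constant FC vector for ", what, " subject(s) ",
         paste(const, collapse = ", "))
  x
}

#' Identifiability matrix
#'
#' Cross-run similarity of FC profiles: entry `I[i, j]` is the Pearson
#' correlation between subject i's run-1 FC vector and subject j's run-2 FC
#' vector. Diagonal entries measure self-similarity across runs,
#' off-diagonal entries between-subject similarity; the matrix is in
#' general asymmetric.
#'
#' @param run1,run2 FC vectors for the two runs: either a list of numeric
#'   vectors (one per subject, same order in both runs) or an `M x Ns`
#'   matrix with subjects in columns.
#' @return `Ns x Ns` numeric matrix (rows = run-1 subjects, columns =
#'   run-2 subjects).
#' @export
identifiability_matrix <- function(run1, run2) {
  a <- .as_fc_stack(run1, "run-1")
  b <- .as_fc_stack(run2, "run-2")
  if (nrow(a) != nrow(b)) stop("runs have different FC vector lengths")
  if (ncol(a) != ncol(b)) stop("runs have different subject counts")
  if (nrow(a) < 3L) stop("FC vectors must have length >= 3")
  stats::cor(a, b)
}

#' Identifiability summary scores
#'
#' `Iself` is the mean of the diagonal of the identifiability matrix,
#' `Iothers` the mean of all `Ns*(Ns-1)` off-diagonal entries (both
#' asymmetric halves), and `Idiff = Iself - Iothers`, reported on the raw
#' correlation scale.
#'
#' @param I identifiability matrix (square, `Ns >= 2`).
#' @return list with `Iself`, `Iothers`, `Idiff`, `var_self`, `var_others`
#'   (sample variances of the two entry sets).
#' @export
idiff <- function(I) {
  I <- as.matrix(I)
  ns <- nrow(I)
  if (ns != ncol(I)) stop("identifiability matrix must be square")
  if (ns < 2L) stop("at least two subjects are required")
  d <- diag(I)
  o <- I[row(I) != col(I)]
  list(Iself = mean(d), Iothers = mean(o), Idiff = mean(d) - mean(o),
       var_self = stats::var(d), var_others = stats::var(o))
}

#' Cohen's d between self- and other-similarities
#'
#' Pooled-variance standardized difference between the diagonal and
#' off-diagonal entries of the identifiability matrix:
#' `d = (Iself - Iothers) / sqrt((var_self + var_others) / 2)`,
#' with sample (n-1) variances.
#'
#' @param I identifiability matrix.
#' @return numeric scalar.
#' @export
cohens_d <- function(I) {
  s <- idiff(I)
  pooled <- (s$var_self + s$var_others) / 2
  if (!is.finite(pooled) || pooled <= 0)
    stop("pooled variance is zero; effect size undefined")
  s$Idiff / sqrt(pooled)
}

#' Top-K identification success rate
#'
#' A subject is identified at level K when the diagonal entry of their row
#' is strictly greater than all but at most `K - 1` off-diagonal entries of
#' that row (i.e. the self-similarity ranks within the top K). Ties with
#' the diagonal count as failures (deterministic, conservative).
#'
#' @param I identifiability matrix.
#' @param K integer, `1 <= K < Ns`.
#' @return list with `rate` (percentage, `100 * identified / Ns`) and
#'   `identified` (integer vector of identified subject indices).
#' @export
success_rate <- function(I, K = 1L) {
  I <- as.matrix(I)
  ns <- nrow(I)
  if (K < 1L || K >= ns) stop("K must satisfy 1 <= K < Ns")
  hit <- vapply(seq_len(ns), function(i) {
    sum(I[i, -i] >= I[i, i]) <= K - 1L
  }, logical(1))
  list(rate = 100 * sum(hit) / ns, identified = which(hit))
}

#' Chance identification level
#'
#' The accuracy expected from random matching: `100 / Ns` percent.
#' Summaries report it to one decimal place.
#'
#' @param Ns number of subjects.
#' @return numeric percentage.
#' @export
chance_level <- function(Ns) {
  if (Ns < 1L) stop("Ns must be >= 1")
  100 / Ns
}

#' Full fingerprint analysis of two runs
#'
#' Computes the identifiability matrix and all summary metrics: Iself,
#' Iothers, Idiff, Cohen's d, the top-K accuracy curve and the chance
#' level.
#'
#' @param run1,run2 FC vectors per subject (list or `M x Ns` matrix; same
#'   subject order in both runs).
#' @param top_k integer vector of K values for the accuracy curve,
#'   default `1:5` (values `>= Ns` are dropped).
#' @return An `identifiability_result`: list with `I`, `Iself`, `Iothers`,
#'   `Idiff`, `var_self`, `var_others`, `cohens_d`, `accuracy_topk` (named
#'   numeric, percentages), `identified` (K = 1 subject indices) and
#'   `chance_level`.
#' @export
fingerprint_analysis <- function(run1, run2, top_k = 1:5) {
  I <- identifiability_matrix(run1, run2)
  ns <- nrow(I)
  s <- idiff(I)
  ks <- top_k[top_k >= 1 & top_k < ns]
  acc <- vapply(ks, function(k) success_rate(I, k)$rate, numeric(1))
  names(acc) <- as.character(ks)
  d <- tryCatch(cohens_d(I), error = function(e) NA_real_)
  structure(
    c(list(I = I), s,
      list(cohens_d = d, accuracy_topk = acc,
           identified = success_rate(I, 1L)$identified,
           chance_level = chance_level(ns))),
    class = "identifiability_result")
}

#' @export
print.identifiability_result <- function(x, ...) {
  ns <- nrow(x$I)
  cat(sprintf("identifiability_result (%d subjects)\n", ns))
  cat(sprintf("  Iself = %.3f  Iothers = %.3f  Idiff = %.3f  Cohen's d = %.2f\n",
              x$Iself, x$Iothers, x$Idiff, x$cohens_d))
  if (length(x$accuracy_topk))
    cat(sprintf("  top-K accuracy (%%): %s  [chance %.1f%%]\n",
                paste(sprintf("K=%s: %.1f", names(x$accuracy_topk),
                              x$accuracy_topk), collapse = ", "),
                x$chance_level))
  invisible(x)
}

#' Differential identifiability by principal-component reconstruction
#'
#' Stacks the `2*Ns` FC vectors of both runs as columns, centers each edge
#' (row) across columns, and for each number of components m reconstructs
#' all columns from the top-m principal components plus the edge means,
#' then recomputes Idiff on the reconstructed profiles. The component count
#' `m*` maximizing Idiff defines the optimally denoised fingerprint; at
#' `m = 2*Ns` the reconstruction is exact and the raw Idiff is recovered.
#'
#' @param run1,run2 FC vectors per subject (list or `M x Ns` matrix).
#' @param m_values integers in `1..2*Ns`; default `1:(2*Ns)`.
#' @param top_k K values passed through to the per-m accuracy computation
#'   (only K = 1 is retained in the curve); default 1.
#' @return A `differential_identifiability_result`: list with
#'   `idiff_by_components` (named numeric over m), `m_star`, `idiff_star`,
#'   and `accuracy_by_components` (K = 1 accuracy per m).
#' @export
pca_differential_identifiability <- function(run1, run2, m_values = NULL,
                                             top_k = 1L) {
  a <- .as_fc_stack(run1, "run-1")
  b <- .as_fc_stack(run2, "run-2")
  if (!identical(dim(a), dim(b))) stop("runs must have identical dimensions")
  ns <- ncol(a)
  if (is.null(m_values)) m_values <- seq_len(2L * ns)
  m_values <- as.integer(m_values)
  if (any(m_values < 1L | m_values > 2L * ns))
    stop("m_values must lie in 1..2*Ns")
  X <- cbind(a, b)
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc, nu = min(dim(Xc)), nv = min(dim(Xc)))
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0))
  curve <- numeric(length(m_values))
  acc <- numeric(length(m_values))
  for (t in seq_along(m_values)) {
    m <- min(m_values[t], rank)
    Um <- sv$u[, seq_len(m), drop = FALSE]
    rec <- Um %*% (crossprod(Um, Xc)) + mu
    r1 <- rec[, seq_len(ns), drop = FALSE]
    r2 <- rec[, ns + seq_len(ns), drop = FALSE]
    I <- stats::cor(r1, r2)
    curve[t] <- idiff(I)$Idiff
    acc[t] <- success_rate(I, 1L)$rate
  }
  names(curve) <- names(acc) <- as.character(m_values)
  best <- which.max(curve)
  structure(
    list(idiff_by_components = curve,
         accuracy_by_components = acc,
         m_star = m_values[best], idiff_star = curve[[best]]),
    class = "differential_identifiability_result")
}

#' @export
print.differential_identifiability_result <- function(x, ...) {
  cat(sprintf(
    "differential identifiability: m* = %d, Idiff* = %.3f (%d m values)\n",
    x$m_star, x$idiff_star, length(x$idiff_by_components)))
  invisible(x)
}
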