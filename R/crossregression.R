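#' Cross-regression between two simultaneously acquired region sets
#'
#' Models every target region's time series as a linear combination of all
#' predictor regions' series (simultaneous acquisition: the time axis is
#' shared). Both sides are mean-centered over time in place of an
#' intercept; coefficients are ordinary least squares with a minimum-norm
#' pseudoinverse solution under rank deficiency, with an optional ridge
#' penalty for predictor counts close to the number of time points. The
#' residuals -- the target activity not linearly explained by the
#' predictors -- are the substrate of residual fingerprinting.
#'
#' @param Y target `run_timeseries` (or matrix), `N_target x T`.
#' @param X predictor `run_timeseries` (or matrix), `N_pred x T`, same T.
#' @param direction label stored with the fit, e.g. `"brain_to_spine"`
#'   (brain predicts spine).
#' @param ridge non-negative ridge penalty added to the predictor Gram
#'   matrix diagonal; default 0 (plain least squares).
#' @return A `cross_regression_fit`: list with `beta`
#'   (`N_target x N_pred`), `fitted` and `residuals` (`N_target x T`,
#'   centered scale), `r_squared` (per target region) and `direction`.
#' @export
fit_cross_regression <- function(Y, X, direction = "", ridge = 0) {
  Ym <- as.matrix(unclass(Y))
  Xm <- as.matrix(unclass(X))
  T <- ncol(Ym)
  if (ncol(Xm) != T)
    stop("Y and X must share the time axis (same number of columns)")
  if (ridge == 0 && T <= nrow(Xm) + 1L)
    stop("T (", T, ") must exceed the number of predictor regions (",
         nrow(Xm), ") + 1; reduce predictor dimensionality or set ridge > 0")
  Yc <- Ym - rowMeans(Ym)
  Xc <- Xm - rowMeans(Xm)
  # beta = Yc Xc' (Xc Xc' + ridge I)^+, per-target-region multiple regression
  G <- tcrossprod(Xc)
  if (ridge > 0) G <- G + diag(ridge, nrow(G))
  sv <- svd(G)
  pos <- sv$d > max(dim(G)) * .Machine$double.eps * max(sv$d, 0)
  Ginv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  beta <- Yc %*% t(Xc) %*% Ginv
  fitted <- beta %*% Xc
  resid <- Yc - fitted
  ss_tot <- rowSums(Yc^2)
  r2 <- ifelse(ss_tot == 0, NA_real_, 1 - rowSums(resid^2) / ss_tot)
  dimnames(beta) <- list(rownames(Ym), rownames(Xm))
  rownames(fitted) <- rownames(resid) <- rownames(Ym)
  structure(
    list(beta = beta, fitted = fitted, residuals = resid,
         r_squared = r2, direction = as.character(direction),
         TR = attr(Y, "TR")),
    class = "cross_regression_fit")
}

#' @export
print.cross_regression_fit <- function(x, ...) {
  cat(sprintf(
    "cross_regression_fit%s: %d target x %d predictor regions, mean R^2 = %.3f\n",
    if (nzchar(x$direction)) paste0(" [", x$direction, "]") else "",
    nrow(x$beta), ncol(x$beta), mean(x$r_squared, na.rm = TRUE)))
  invisible(x)
}

#' Fingerprint analysis of cross-regression residuals
#'
#' Builds FC profiles from the residual time series of per-subject
#' cross-regression fits (one fit per subject per run) and runs the full
#' identifiability pipeline on them. The result quantifies how much
#' subject-specific signature survives once the predictor regions' linear
#' contribution is removed.
#'
#' @param fits_run1,fits_run2 lists of `cross_regression_fit`, one per
#'   subject, same subject order in both runs.
#' @param top_k K values for the accuracy curve, default `1:5`.
#' @return An `identifiability_result` (see [fingerprint_analysis()]).
#' @export
residual_fingerprint <- function(fits_run1, fits_run2, top_k = 1:5) {
  if (length(fits_run1) != length(fits_run2))
    stop("runs must have the same number of subjects")
  vec_of <- function(fit) {
    stopifnot(inherits(fit, "cross_regression_fit"))
    .vec_upper(compute_fc(fit$residuals))
  }
  run1 <- vapply(fits_run1, vec_of, numeric(
    nrow(fits_run1[[1]]$residuals) * (nrow(fits_run1[[1]]$residuals) - 1) / 2))
  run2 <- vapply(fits_run2, vec_of, numeric(nrow(run1)))
  fingerprint_analysis(run1, run2, top_k = top_k)
}
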