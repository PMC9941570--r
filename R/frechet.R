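#' Raw covariance matrices from visit residuals
#'
#' Each visit contributes the rank-at-most-one matrix
#' \eqn{\hat C_i = (Y_i - \hat\mu(T_i)) (Y_i - \hat\mu(T_i))'}, the
#' residual outer product around the smoothed mean growth curve.  These
#' matrices, paired with the visit's covariate value(s), are the responses
#' of the Frechet regression.
#'
#' @param data cohort table (one row per visit).
#' @param mu an `scn_meanfit` from [estimate_mean_function()].
#' @param age name of the age column.
#' @param elc optional name of a score column; when given, each raw
#'   covariance carries the covariate pair `(age, score)`.
#' @return an object of class `scn_rawcov_list`: a list with one element
#'   per visit, each holding `covariate` and `matrix`.  The underlying
#'   residual matrix is attached as attribute `"resid"` (visits by ROIs).
#' @export
compute_raw_covariances <- function(data, mu, age = "age", elc = NULL) {
  stopifnot(inherits(mu, "scn_meanfit"))
  ages <- as.numeric(data[[age]])
  Y <- as.matrix(data[, mu$rois, drop = FALSE])
  storage.mode(Y) <- "double"
  resid <- Y - predict(mu, ages)
  cov_vals <- if (is.null(elc)) ages else cbind(age = ages,
                                                elc = as.numeric(data[[elc]]))
  out <- lapply(seq_len(nrow(resid)), function(i) {
    r <- resid[i, ]
    list(covariate = if (is.null(elc)) ages[i] else cov_vals[i, ],
         matrix = tcrossprod(r))
  })
  structure(out, resid = resid, covariates = cov_vals, rois = mu$rois,
            class = "scn_rawcov_list")
}

#' @export
print.scn_rawcov_list <- function(x, ...) {
  m <- nrow(x[[1]]$matrix)
  cat(sprintf("<scn_rawcov_list: %d visits, %d x %d matrices>\n",
              length(x), m, m))
  invisible(x)
}

#' Nearest positive semidefinite matrix
#'
#' Projects a symmetric matrix onto the cone of positive semidefinite
#' matrices under the Frobenius norm by setting negative eigenvalues to
#' zero.  Needed because local-linear weights can be negative, so the
#' kernel-weighted average of raw covariances can leave the cone.  The
#' projection is idempotent and leaves PSD inputs unchanged.
#'
#' @param x symmetric numeric matrix (asymmetry beyond `1e-8` is an error;
#'   smaller asymmetry is symmetrized away first).
#' @return the projected matrix.
#' @examples
#' nearest_psd(matrix(c(1, 2, 2, 1), 2))  # eigenvalues 3, -1 -> clip
#' @export
nearest_psd <- function(x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("matrix has non-finite entries")
  if (nrow(x) != ncol(x)) stop("matrix must be square")
  if (max(abs(x - t(x))) > 1e-8) stop("matrix is not symmetric")
  cpp_nearest_psd(x)
}

#' Weighted Frechet mean of covariance matrices under the Frobenius metric
#'
#' The minimizer of \eqn{\sum_i w_i \, d_F^2(C, \hat C_i)} over the PSD
#' cone is obtained in closed form: the weighted average
#' \eqn{\sum_i w_i \hat C_i / \sum_i w_i} followed by projection onto the
#' cone ([nearest_psd()]).  Weights may be negative (local-linear weights
#' are, near the design boundary) as long as they sum to a positive value.
#'
#' @param matrices list of symmetric matrices of a common dimension.
#' @param weights numeric weights, one per matrix; `sum(weights)` must be
#'   positive.
#' @return the weighted Frechet mean (symmetric PSD matrix).
#' @export
weighted_frechet_mean <- function(matrices, weights) {
  stopifnot(length(matrices) == length(weights))
  sw <- sum(weights)
  if (!is.finite(sw) || sw <= 1e-12)
    stop("weights are numerically zero (or negative) in total")
  acc <- matrices[[1]] * weights[1]
  for (i in seq_along(matrices)[-1]) acc <- acc + matrices[[i]] * weights[i]
  nearest_psd(acc / sw)
}

#' Local Frechet regression estimate at a query point
#'
#' Estimates the conditional covariance matrix \eqn{\hat\Sigma(t)} (or
#' \eqn{\hat\Sigma(t, z)} with a second covariate) by the kernel-weighted
#' Frobenius Frechet mean of the raw covariance matrices, using
#' [local_weights()] and [weighted_frechet_mean()].
#'
#' @param query scalar age, or length-2 `(age, score)`.
#' @param raws an `scn_rawcov_list` from [compute_raw_covariances()].
#' @param kernel a [kernel_spec()] or family name.
#' @param bandwidths bandwidth(s); default rule-of-thumb per dimension.
#' @return symmetric PSD matrix of class `scn_cov` with attributes `query`
#'   and `ess` (mean absolute weight, an effective-sample-size diagnostic).
#' @export
frechet_covariance_at <- function(query, raws, kernel = "gaussian",
                                  bandwidths = NULL) {
  stopifnot(inherits(raws, "scn_rawcov_list"))
  covariates <- attr(raws, "covariates")
  w <- local_weights(query, covariates, kernel, bandwidths)
  est <- weighted_frechet_mean(lapply(raws, `[[`, "matrix"), as.numeric(w))
  rownames(est) <- colnames(est) <- attr(raws, "rois")
  structure(est, query = as.numeric(query),
            ess = mean(abs(as.numeric(w))), class = c("scn_cov", "matrix"))
}
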