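#' Local-linear estimate of the per-region mean growth curves
#'
#' Fits, for every region of interest (ROI), the conditional mean volume
#' \eqn{\mu_j(t) = E(Y_j \mid T = t)} by a local-linear kernel smoother.
#' The same kernel family is used as in the Frechet regression step, so a
#' single set of weight identities governs the whole pipeline.  The
#' smoother reproduces constants and linear functions exactly.
#'
#' @param data a cohort table (one row per visit) as produced by
#'   [generate_cohort()] or [read_cohort()].
#' @param rois character vector of ROI volume columns; default: all columns
#'   starting with `"roi"`.
#' @param age name of the age column (years).
#' @param kernel a [kernel_spec()] or family name.
#' @param bandwidth positive bandwidth in years; default is the
#'   rule-of-thumb `1.06 sd(age) n^{-1/5}`, optionally replaced by
#'   leave-one-out cross-validation when `cv = TRUE`.
#' @param cv if `TRUE`, select the bandwidth by leave-one-out
#'   cross-validation over a geometric grid around the rule-of-thumb value
#'   (the shortcut formula for linear smoothers is used, so no refitting
#'   loop over observations is needed).
#' @return an object of class `scn_meanfit`; evaluate it with `predict()`.
#' @seealso [compute_raw_covariances()]
#' @export
estimate_mean_function <- function(data, rois = NULL, age = "age",
                                   kernel = "gaussian", bandwidth = NULL,
                                   cv = FALSE) {
  rois <- resolve_rois(data, rois)
  ages <- as.numeric(data[[age]])
  if (length(unique(ages)) < 3)
    stop("mean smoother needs at least 3 distinct ages")
  Y <- as.matrix(data[, rois, drop = FALSE])
  storage.mode(Y) <- "double"
  if (anyNA(Y) || !all(is.finite(Y))) stop("volumes must be finite")
  if (is.null(bandwidth)) bandwidth <- rule_of_thumb_bandwidth(ages)
  stopifnot(bandwidth > 0)
  if (cv) bandwidth <- loo_cv_bandwidth(ages, Y, kernel, bandwidth)
  structure(list(ages = ages, Y = Y, rois = rois,
                 kernel = as_kernel_spec(kernel), bandwidth = bandwidth),
            class = "scn_meanfit")
}

# leave-one-out CV using the linear-smoother shortcut: the LOO residual is
# (y_i - mu_hat(T_i)) / (1 - l_ii), l_ii = s_i(T_i)/n the hat diagonal
loo_cv_bandwidth <- function(ages, Y, kernel, h0,
                             grid = h0 * 2^seq(-1.5, 1.5, length.out = 7)) {
  n <- length(ages)
  score <- vapply(grid, function(h) {
    sse <- 0
    for (i in seq_len(n)) {
      w <- tryCatch(local_weights(ages[i], ages, kernel, h),
                    error = function(e) NULL)
      if (is.null(w)) return(Inf)
      mu_i <- drop(crossprod(as.numeric(w), Y)) / n
      lii <- as.numeric(w)[i] / n
      if (lii >= 1 - 1e-8) return(Inf)
      sse <- sse + sum(((Y[i, ] - mu_i) / (1 - lii))^2)
    }
    sse
  }, numeric(1))
  if (all(!is.finite(score)))
    stop("leave-one-out CV failed at every candidate bandwidth")
  grid[which.min(score)]
}

#' Evaluate a fitted mean function
#'
#' @param object an `scn_meanfit`.
#' @param newages ages (years) at which to evaluate; default: the fit ages.
#' @param ... unused.
#' @return numeric matrix, `length(newages)` rows by one column per ROI.
#' @export
predict.scn_meanfit <- function(object, newages = NULL, ...) {
  if (is.null(newages)) newages <- object$ages
  n <- length(object$ages)
  out <- matrix(NA_real_, length(newages), ncol(object$Y),
                dimnames = list(NULL, object$rois))
  for (i in seq_along(newages)) {
    w <- tryCatch(
      local_weights(newages[i], object$ages, object$kernel,
                    object$bandwidth),
      error = function(e) {
        stop(sprintf("mean smoother design is singular at age %s: %s",
                     format(newages[i]), conditionMessage(e)))
      })
    out[i, ] <- drop(crossprod(as.numeric(w), object$Y)) / n
  }
  out
}

#' @export
print.scn_meanfit <- function(x, ...) {
  cat(sprintf(
    "<scn_meanfit: %d ROIs, n = %d visits, %s kernel, h = %.4g years>\n",
    ncol(x$Y), length(x$ages), x$kernel$family, x$bandwidth))
  invisible(x)
}

resolve_rois <- function(data, rois) {
  if (is.null(rois)) rois <- grep("^roi", names(data), value = TRUE)
  if (length(rois) < 2)
    stop("need at least two ROI volume columns (names starting with 'roi' ",
         "or given via `rois`)")
  missing <- setdiff(rois, names(data))
  if (length(missing))
    stop("ROI columns not found: ", paste(missing, collapse = ", "))
  rois
}
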