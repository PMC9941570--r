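#' Local-linear regression weights
#'
#' Computes the local-linear weight vector used by both the mean smoother
#' and the Frechet regression step.  With one covariate (age),
#' \deqn{s_i(t, h) = \frac{1}{\hat\sigma_0^2} K_h(T_i - t)
#'   [\hat b_2 - \hat b_1 (T_i - t)],}
#' where \eqn{\hat b_j = n^{-1} \sum_i K_h(T_i - t)(T_i - t)^j} and
#' \eqn{\hat\sigma_0^2 = \hat b_0 \hat b_2 - \hat b_1^2}.  With two
#' covariates (age and a score), a product kernel is used and
#' \deqn{s_i(x, h) = \frac{K_h(X_i - x) [1 - \hat b_1' \hat b_2^{-1}
#'   (X_i - x)]}{\hat b_0 - \hat b_1' \hat b_2^{-1} \hat b_1}.}
#'
#' The weights always satisfy \eqn{n^{-1} \sum_i s_i = 1} and the
#' first-moment orthogonality \eqn{n^{-1}\sum_i s_i (X_i - x) = 0}
#' (componentwise), and they may be negative near the boundary of the
#' design.
#'
#' @param query scalar age, or length-2 numeric `(age, score)`.
#' @param covariates numeric vector of ages, or a 2-column matrix with one
#'   row per observation.
#' @param kernel a [kernel_spec()] or family name.
#' @param bandwidths positive bandwidth (scalar, or length 2 for the
#'   bivariate case, one per covariate dimension).
#' @return numeric weight vector with attributes `query` and `bandwidths`.
#' @examples
#' w <- local_weights(5, c(4, 5, 6), bandwidths = 1)
#' mean(w)  # 1
#' @export
local_weights <- function(query, covariates, kernel = "gaussian",
                          bandwidths = NULL) {
  code <- kernel_code(kernel)
  if (is.matrix(covariates) || length(query) == 2) {
    X <- as.matrix(covariates)
    if (ncol(X) != 2 || length(query) != 2)
      stop("bivariate weights need a 2-column covariate matrix and a ",
           "length-2 query")
    if (is.null(bandwidths))
      bandwidths <- c(rule_of_thumb_bandwidth(X[, 1]),
                      rule_of_thumb_bandwidth(X[, 2]))
    if (length(bandwidths) == 1) bandwidths <- rep(bandwidths, 2)
    stopifnot(all(bandwidths > 0))
    w <- cpp_local_weights_2d(X, as.numeric(query), as.numeric(bandwidths),
                              code)
  } else {
    T <- as.numeric(covariates)
    if (length(T) < 2) stop("need at least two observations")
    if (is.null(bandwidths)) bandwidths <- rule_of_thumb_bandwidth(T)
    stopifnot(length(bandwidths) == 1, bandwidths > 0)
    w <- cpp_local_weights_1d(T, as.numeric(query), bandwidths, code)
  }
  if (!isTRUE(attr(w, "ok")))
    stop(sprintf(paste0("local design is degenerate at query point (%s); ",
                        "increase the bandwidth"),
                 paste(format(query), collapse = ", ")))
  attr(w, "ok") <- NULL
  structure(as.numeric(w), query = as.numeric(query),
            bandwidths = as.numeric(bandwidths), class = "scn_weights")
}

#' @export
print.scn_weights <- function(x, ...) {
  cat(sprintf("<scn_weights: n = %d, query = (%s), h = (%s)>\n",
              length(x), paste(format(attr(x, "query")), collapse = ", "),
              paste(format(attr(x, "bandwidths")), collapse = ", ")))
  print(as.numeric(x), ...)
  invisible(x)
}
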