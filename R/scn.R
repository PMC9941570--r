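#' Standardize a covariance estimate to a correlation matrix
#'
#' \eqn{\hat R = D^{-1/2} \hat\Sigma D^{-1/2}} with
#' \eqn{D = \mathrm{diag}(\hat\Sigma)}.  Entries within numerical noise of
#' the \eqn{[-1, 1]} bounds are clipped; the diagonal is exactly 1.
#'
#' @param sigma covariance matrix (e.g. from [frechet_covariance_at()]).
#' @param floor smallest admissible diagonal entry; at or below it the
#'   variance is treated as degenerate (a symptom of oversmoothing or of an
#'   ROI with no residual variation) and an error names the ROI.
#' @return correlation matrix of class `scn_corr` (unit diagonal,
#'   symmetric), carrying over the `query` attribute when present.
#' @export
cov_to_corr <- function(sigma, floor = 1e-12) {
  s <- as.matrix(sigma)
  d <- diag(s)
  labs <- rownames(s)
  if (is.null(labs)) labs <- sprintf("roi_%03d", seq_along(d))
  bad <- which(!(d > floor))
  if (length(bad))
    stop(sprintf("degenerate variance (<= %g) at ROI %s; the covariance is
oversmoothed or the region has no residual variation",
                 floor, paste(labs[bad], collapse = ", ")))
  r <- s / sqrt(tcrossprod(d))
  r[r > 1 & r < 1 + 1e-8] <- 1
  r[r < -1 & r > -1 - 1e-8] <- -1
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  dimnames(r) <- list(labs, labs)
  structure(r, query = attr(sigma, "query"), class = c("scn_corr", "matrix"))
}

#' Threshold a correlation matrix into a weighted SCN adjacency matrix
#'
#' Value-retaining thresholding: entries at or above `theta` keep their
#' correlation value, all others (including every negative correlation,
#' since `theta > 0`) are set to zero; the diagonal is zero.  Networks are
#' not binarized.
#'
#' @param corr correlation matrix.
#' @param theta threshold in (0, 1).
#' @return adjacency matrix of class `scn_adj` with attributes `theta` and
#'   `query`.
#' @export
threshold_network <- function(corr, theta) {
  stopifnot(is.numeric(theta), length(theta) == 1, theta > 0, theta < 1)
  a <- as.matrix(corr)
  a[a < theta] <- 0
  diag(a) <- 0
  structure(a, theta = theta, query = attr(corr, "query"),
            class = c("scn_adj", "matrix"))
}

#' Default threshold grid
#'
#' Thresholds 0.60 to 0.90 in steps of 0.05 (7 values): the lower bound
#' enforces sparsity, the upper bound avoids fragmenting the network.
#'
#' @return strictly increasing numeric vector in (0, 1).
#' @export
default_thresholds <- function() seq(0.60, 0.90, by = 0.05)

check_thresholds <- function(thresholds) {
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1,
            all(thresholds > 0), all(thresholds < 1),
            all(diff(thresholds) > 0))
  as.numeric(thresholds)
}

#' Build SCN adjacency matrices over an age and threshold grid
#'
#' Orchestrates mean smoothing, raw covariances, Frechet regression,
#' standardization and thresholding for every (group-or-score, age,
#' threshold) cell.  Ages outside 1 to 9 years are allowed but flagged in the
#' log, since estimates close to the age-range boundary are less reliable.
#'
#' @param object a fitted [frechet_scn()] model.
#' @param ages evaluation ages (default 1 to 9 years).
#' @param thresholds threshold grid (default [default_thresholds()]).
#' @param scores evaluation scores for a bivariate (age, score) fit;
#'   defaults to the model's `scores` setting or `c(80, 100, 120)`.
#' @return an object of class `scn_series`: a list of cells, each with
#'   `group`, `age`, `theta`, and the `adjacency` matrix; correlation
#'   matrices are kept per (group, age) under `$corr`.
#' @export
build_scn_series <- function(object, ages = 1:9,
                             thresholds = default_thresholds(),
                             scores = NULL) {
  stopifnot(inherits(object, "frechet_scn"))
  thresholds <- check_thresholds(thresholds)
  rng <- range(object$ages)
  if (any(ages < rng[1] | ages > rng[2]))
    stop("evaluation ages must lie inside the observed age range [",
         format(rng[1]), ", ", format(rng[2]), "]")
  if (any(ages < 1 | ages > 9))
    scn_log("note: evaluation ages outside [1, 9] are near the design %s",
            "boundary; estimates there are less stable")
  cells <- list()
  corrs <- list()
  for (g in series_groups(object, scores)) {
    for (a in ages) {
      r <- tryCatch(
        predict(object, ages = a, scores = g$score, groups = g$level,
                what = "correlation"),
        error = function(e) {
          stop(sprintf("SCN cell (group %s, age %s) failed: %s", g$label,
                       format(a), conditionMessage(e)), call. = FALSE)
        })
      corrs[[g$label]][[as.character(a)]] <- r
      for (th in thresholds) {
        cells[[length(cells) + 1]] <-
          list(group = g$label, age = a, theta = th,
               adjacency = threshold_network(r, th))
      }
    }
  }
  structure(list(cells = cells, corr = corrs,
                 groups = vapply(series_groups(object, scores), `[[`,
                                 character(1), "label"),
                 ages = as.numeric(ages), thresholds = thresholds,
                 rois = object$rois),
            class = "scn_series")
}

# enumerate evaluation units: group levels for a grouped fit, score values
# for a bivariate fit, a single pooled unit otherwise
series_groups <- function(object, scores = NULL) {
  if (!is.null(object$elc)) {
    if (is.null(scores)) scores <- object$scores
    lapply(scores, function(z)
      list(label = sprintf("elc=%g", z), level = NULL, score = z))
  } else if (!is.null(object$group)) {
    lapply(levels(object$group), function(l)
      list(label = l, level = l, score = NULL))
  } else {
    list(list(label = "all", level = NULL, score = NULL))
  }
}

#' @export
print.scn_series <- function(x, ...) {
  cat(sprintf(
    "<scn_series: %d cells = %d group(s) x %d age(s) x %d threshold(s)>\n",
    length(x$cells), length(x$groups), length(x$ages),
    length(x$thresholds)))
  invisible(x)
}

#' Extract one adjacency matrix from an SCN series
#'
#' @param series an `scn_series`.
#' @param group group (or `"elc=z"`) label; may be omitted when the series
#'   has a single group.
#' @param age,theta cell coordinates (must match grid values exactly).
#' @return the `scn_adj` matrix of that cell.
#' @export
series_cell <- function(series, age, theta, group = NULL) {
  stopifnot(inherits(series, "scn_series"))
  if (is.null(group)) {
    if (length(series$groups) > 1) stop("`group` is required")
    group <- series$groups[1]
  }
  for (cell in series$cells)
    if (cell$group == group && cell$age == age &&
        isTRUE(all.equal(cell$theta, theta)))
      return(cell$adjacency)
  stop(sprintf("no cell (group %s, age %s, theta %s) in series", group,
               format(age), format(theta)))
}
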