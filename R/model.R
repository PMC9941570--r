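#' Fit a local Frechet regression model for evolving SCNs
#'
#' The central model object of the package.  Fitting consists of (i) a
#' local-linear estimate of the per-ROI mean growth curves on the pooled
#' sample, (ii) visit residuals, whose outer products are the rank-one raw
#' covariance responses, and (iii) the bookkeeping (kernel, bandwidths,
#' grouping or score covariate) needed to evaluate the Frechet regression
#' estimate \eqn{\hat\Sigma} at any age.  Evaluation happens lazily
#' through [predict.frechet_scn()], [build_scn_series()] and
#' [scn_measure_curves()].
#'
#' Visits are treated as independent observations (the estimator's working
#' assumption for sparse accelerated-longitudinal designs, where most
#' children contribute one visit).  With `group`, estimation is carried out
#' within each group using the pooled mean fit by default; with `elc`, age
#' and score enter jointly through a product kernel.
#'
#' @param data cohort table, one row per visit ([generate_cohort()],
#'   [read_cohort()], or any data frame with the same layout).
#' @param rois ROI volume columns (default: names starting with `"roi"`).
#' @param age name of the age column (years).
#' @param elc optional name of the score column; switches to the bivariate
#'   (age, score) model.  Mutually exclusive with `group`.
#' @param group optional grouping: the name of a factor column, or
#'   `"sex_mated"` to derive the standard four groups (sex by maternal
#'   education dichotomized at level 6), or a factor vector with one entry
#'   per visit.
#' @param kernel a [kernel_spec()] or family name.
#' @param bandwidth Frechet-regression age bandwidth.  Default: the
#'   rule-of-thumb `1.06 sd(age) n^{-1/5}`, with the pooled age spread and
#'   the group's own sample size for grouped fits (so the bandwidth is
#'   invariant under label permutations).
#' @param elc_bandwidth score bandwidth (bivariate fits); rule-of-thumb by
#'   default.
#' @param mean_bandwidth bandwidth of the mean smoother (rule-of-thumb by
#'   default); `cv_mean = TRUE` selects it by leave-one-out CV instead.
#' @param cv_mean select the mean-smoother bandwidth by LOO CV.
#' @param scores default evaluation scores for bivariate fits.
#' @param mean_per_group refit the mean curves within each group instead
#'   of pooling (the mean function is label-independent under the null, so
#'   pooling is the default).
#' @return an object of class `frechet_scn`.
#' @examples
#' cfg <- synthetic_config(n_children = 80, m_rois = 6, seed = 7)
#' fit <- frechet_scn(generate_cohort(cfg))
#' fit
#' R5 <- predict(fit, ages = 5)
#' @export
frechet_scn <- function(data, rois = NULL, age = "age", elc = NULL,
                        group = NULL, kernel = "gaussian",
                        bandwidth = NULL, elc_bandwidth = NULL,
                        mean_bandwidth = NULL, cv_mean = FALSE,
                        scores = c(80, 100, 120),
                        mean_per_group = FALSE) {
  cl <- match.call()
  rois <- resolve_rois(data, rois)
  ages <- as.numeric(data[[age]])
  if (anyNA(ages)) stop("missing ages")
  if (!is.null(elc) && !is.null(group))
    stop("`elc` and `group` are mutually exclusive")

  grp <- NULL
  if (!is.null(group)) {
    grp <- if (is.factor(group) || (is.character(group) &&
                                    length(group) == nrow(data) &&
                                    nrow(data) > 1)) {
      factor(group)
    } else if (identical(group, "sex_mated")) {
      sex_mated_groups(data)
    } else if (is.character(group) && length(group) == 1) {
      if (!group %in% names(data)) stop("no column called '", group, "'")
      factor(data[[group]])
    } else stop("`group` must be a column name, 'sex_mated', or a factor")
    if (length(grp) != nrow(data))
      stop("`group` must have one entry per visit")
    if (any(table(grp) == 0)) stop("empty group level")
  }

  elc_vals <- NULL
  if (!is.null(elc)) {
    if (!elc %in% names(data)) stop("no column called '", elc, "'")
    elc_vals <- as.numeric(data[[elc]])
    if (anyNA(elc_vals)) stop("missing scores in column '", elc, "'")
  }

  if (mean_per_group && !is.null(grp)) {
    resid <- matrix(NA_real_, nrow(data), length(rois),
                    dimnames = list(NULL, rois))
    meanfit <- list()
    for (l in levels(grp)) {
      idx <- which(grp == l)
      mf <- estimate_mean_function(data[idx, , drop = FALSE], rois, age,
                                   kernel, mean_bandwidth, cv_mean)
      meanfit[[l]] <- mf
      resid[idx, ] <- as.matrix(data[idx, rois]) - predict(mf, ages[idx])
    }
  } else {
    meanfit <- estimate_mean_function(data, rois, age, kernel,
                                      mean_bandwidth, cv_mean)
    resid <- as.matrix(data[, rois]) - predict(meanfit, ages)
  }
  storage.mode(resid) <- "double"

  n <- length(ages)
  sd_age <- stats::sd(ages)
  if (is.null(bandwidth)) {
    h_by_group <- if (is.null(grp)) 1.06 * sd_age * n^(-1 / 5)
      else 1.06 * sd_age * as.numeric(table(grp))^(-1 / 5)
  } else {
    h_by_group <- rep(bandwidth, if (is.null(grp)) 1 else nlevels(grp))
  }
  h_age <- if (is.null(bandwidth)) 1.06 * sd_age * n^(-1 / 5) else bandwidth
  h_elc <- NULL
  if (!is.null(elc_vals)) {
    h_elc <- if (is.null(elc_bandwidth))
      rule_of_thumb_bandwidth(elc_vals) else elc_bandwidth
  }

  structure(list(
    call = cl, rois = rois, ages = ages, elc = elc_vals, group = grp,
    resid = resid, meanfit = meanfit, kernel = as_kernel_spec(kernel),
    scores = scores,
    bandwidths = list(
      mean = if (mean_per_group && !is.null(grp))
        vapply(meanfit, `[[`, numeric(1), "bandwidth")
      else meanfit$bandwidth,
      age = h_age, age_by_group = h_by_group, elc = h_elc)),
    class = "frechet_scn")
}

#' Derive the four sex-by-maternal-education groups
#'
#' Maternal education (ordinal 1-7) is dichotomized at 6 (bachelor's
#' degree): levels below 6 are "low", 6 and above "high"; crossed with sex
#' this yields `F_low`, `F_high`, `M_low`, `M_high`.
#'
#' @param data cohort table with `sex` and `mated` columns.
#' @param cut dichotomization level (default 6).
#' @return factor with the four levels; errors if any is empty.
#' @export
sex_mated_groups <- function(data, cut = 6) {
  stopifnot(all(c("sex", "mated") %in% names(data)))
  med <- ifelse(as.numeric(data$mated) >= cut, "high", "low")
  g <- factor(paste(data$sex, med, sep = "_"),
              levels = c("F_low", "F_high", "M_low", "M_high"))
  if (anyNA(g)) stop("sex must be 'F' or 'M'")
  empty <- levels(g)[table(g) == 0]
  if (length(empty))
    stop("empty group(s): ", paste(empty, collapse = ", "))
  g
}

#' Predict covariance, correlation, or adjacency matrices
#'
#' Evaluates the local Frechet regression at the requested ages (and, for
#' bivariate fits, scores).  Returns a single matrix when one cell is
#' requested, otherwise a nested list indexed by group/score then age.
#'
#' @param object a fitted [frechet_scn()] model.
#' @param ages evaluation ages.
#' @param scores evaluation scores (bivariate fits only); default: the
#'   model's `scores` setting.
#' @param groups group levels to evaluate (grouped fits; default all).
#' @param what `"correlation"`, `"covariance"`, or `"adjacency"`.
#' @param theta threshold for `what = "adjacency"`.
#' @param ... unused.
#' @return matrix or nested list of matrices.
#' @export
predict.frechet_scn <- function(object, ages, scores = NULL, groups = NULL,
                                what = c("correlation", "covariance",
                                         "adjacency"),
                                theta = 0.8, ...) {
  what <- match.arg(what)
  want_corr <- what != "covariance"
  kcode <- kernel_code(object$kernel)
  out <- list()
  if (!is.null(object$elc)) {
    if (is.null(scores)) scores <- object$scores
    X <- cbind(object$ages, object$elc)
    for (z in scores) {
      lab <- sprintf("elc=%g", z)
      for (a in ages) {
        res <- cpp_frechet_corr_at2(object$resid, X, c(a, z),
                                    c(object$bandwidths$age,
                                      object$bandwidths$elc), kcode,
                                    want_corr)
        out[[lab]][[as.character(a)]] <-
          finish_prediction(res, object$rois, c(a, z), what, theta)
      }
    }
  } else {
    if (!is.null(scores))
      stop("`scores` only applies to bivariate (age, score) fits")
    levs <- if (is.null(object$group)) "all" else levels(object$group)
    if (is.null(groups)) groups <- levs
    if (!all(groups %in% levs))
      stop("unknown group level(s): ",
           paste(setdiff(groups, levs), collapse = ", "))
    for (l in groups) {
      idx <- if (is.null(object$group)) seq_along(object$ages)
             else which(object$group == l)
      h <- object$bandwidths$age_by_group[
        if (is.null(object$group)) 1 else match(l, levs)]
      for (a in ages) {
        res <- cpp_frechet_corr_at(object$resid[idx, , drop = FALSE],
                                   object$ages[idx], a, h, kcode,
                                   want_corr)
        out[[l]][[as.character(a)]] <-
          finish_prediction(res, object$rois, a, what, theta)
      }
    }
  }
  if (length(out) == 1 && length(out[[1]]) == 1) return(out[[1]][[1]])
  if (length(out) == 1) return(out[[1]])
  out
}

finish_prediction <- function(res, rois, query, what, theta) {
  if (!isTRUE(res$ok)) {
    msg <- switch(res$reason,
      degenerate_weights = "local design is degenerate (bandwidth too small)",
      zero_weight_sum = "weights sum to zero",
      zero_variance = "an ROI has degenerate variance at this query point",
      res$reason)
    stop(sprintf("prediction failed at (%s): %s",
                 paste(format(query), collapse = ", "), msg))
  }
  if (what == "covariance") {
    m <- res$cov
    dimnames(m) <- list(rois, rois)
    return(structure(m, query = query, ess = res$ess,
                     class = c("scn_cov", "matrix")))
  }
  r <- res$corr
  dimnames(r) <- list(rois, rois)
  r <- structure(r, query = query, class = c("scn_corr", "matrix"))
  if (what == "adjacency") threshold_network(r, theta) else r
}

#' @export
print.frechet_scn <- function(x, ...) {
  cat("Local Frechet regression of structural covariance\n")
  cat(sprintf("  %d visits, %d ROIs, ages %.2f-%.2f years\n",
              length(x$ages), length(x$rois), min(x$ages), max(x$ages)))
  if (!is.null(x$group))
    cat("  groups:", paste(sprintf("%s (%d)", levels(x$group),
                                   table(x$group)), collapse = ", "), "\n")
  if (!is.null(x$elc))
    cat(sprintf("  bivariate covariate: age and score (h = %.3g, %.3g)\n",
                x$bandwidths$age, x$bandwidths$elc))
  cat(sprintf("  kernel: %s; age bandwidth: %s years\n", x$kernel$family,
              paste(format(round(x$bandwidths$age_by_group %||%
                                   x$bandwidths$age, 3)),
                    collapse = "/")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.frechet_scn <- function(object, ...) {
  s <- list(
    n_visits = length(object$ages),
    n_children = NA_integer_,
    m_rois = length(object$rois),
    age_range = range(object$ages),
    kernel = object$kernel$family,
    bandwidths = object$bandwidths,
    groups = if (is.null(object$group)) NULL else table(object$group),
    bivariate = !is.null(object$elc))
  class(s) <- "summary.frechet_scn"
  s
}

#' @export
print.summary.frechet_scn <- function(x, ...) {
  cat("Local Frechet regression of structural covariance\n")
  cat(sprintf("  visits: %d   ROIs: %d   ages: %.2f-%.2f years\n",
              x$n_visits, x$m_rois, x$age_range[1], x$age_range[2]))
  cat(sprintf("  kernel: %s\n", x$kernel))
  cat(sprintf("  mean-smoother bandwidth: %s\n",
              paste(format(round(unlist(x$bandwidths$mean), 3)),
                    collapse = "/")))
  cat(sprintf("  Frechet age bandwidth: %s\n",
              paste(format(round(x$bandwidths$age_by_group %||%
                                   x$bandwidths$age, 3)),
                    collapse = "/")))
  if (!is.null(x$bandwidths$elc))
    cat(sprintf("  score bandwidth: %.3g\n", x$bandwidths$elc))
  if (!is.null(x$groups)) {
    cat("  group sizes:\n")
    print(x$groups)
  }
  invisible(x)
}

#' @export
residuals.frechet_scn <- function(object, ...) object$resid

#' @export
fitted.frechet_scn <- function(object, ...) {
  if (inherits(object$meanfit, "scn_meanfit"))
    return(predict(object$meanfit, object$ages))
  out <- matrix(NA_real_, length(object$ages), length(object$rois),
                dimnames = list(NULL, object$rois))
  for (l in names(object$meanfit)) {
    idx <- which(object$group == l)
    out[idx, ] <- predict(object$meanfit[[l]], object$ages[idx])
  }
  out
}

#' Plot threshold-averaged measure curves of a fitted model
#'
#' @param x a fitted [frechet_scn()] model.
#' @param measure `"modularity"` or `"global_efficiency"`.
#' @param ages,thresholds,scores,length_rule,seed passed to
#'   [scn_measure_curves()].
#' @param ... further arguments to [graphics::matplot()].
#' @return the curve data frame, invisibly.
#' @export
plot.frechet_scn <- function(x, measure = "modularity", ages = 1:9,
                             thresholds = default_thresholds(),
                             scores = NULL, length_rule = "weight",
                             seed = 1L, ...) {
  curves <- scn_measure_curves(x, measure, ages, thresholds, scores,
                               length_rule, seed)
  groups <- unique(curves$group)
  mat <- sapply(groups, function(g) curves$value[curves$group == g])
  graphics::matplot(ages, mat, type = "b", pch = seq_along(groups),
                    lty = 1, xlab = "age (years)",
                    ylab = sprintf("threshold-averaged %s", measure), ...)
  graphics::legend("topleft", legend = groups, pch = seq_along(groups),
                   col = seq_along(groups), lty = 1, bty = "n")
  invisible(curves)
}
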