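#' Integrated network measure from an age onward
#'
#' The right-tail Riemann sum
#' \deqn{I(t_j) = \sum_{l=j}^N \bar M(t_l) (t_l - t_{l-1}), \quad t_0 = 0,}
#' of a threshold-averaged measure curve: the cumulative measure from age
#' \eqn{t_j} to the last evaluation age, with the first spacing taken from
#' age 0.  This is the quantity whose between-group variance is the
#' permutation test statistic, so each age's test concerns the evolution
#' of the network from that age onward rather than at that age alone.
#'
#' @param values measure values \eqn{\bar M(t_1), \ldots, \bar M(t_N)}.
#' @param ages strictly increasing evaluation ages \eqn{t_1 < \ldots <
#'   t_N}.
#' @param j start index (1-based).
#' @return the integral (measure units times years).
#' @export
integrated_measure <- function(values, ages, j) {
  stopifnot(length(values) == length(ages), all(diff(ages) > 0))
  N <- length(ages)
  if (!(j >= 1 && j <= N)) stop("start index j out of range 1..", N)
  dt <- diff(c(0, ages))
  sum(values[j:N] * dt[j:N])
}

# all start indices at once: I(t_j) for j = 1..N
integrated_measures_all <- function(values, ages) {
  dt <- diff(c(0, ages))
  rev(cumsum(rev(values * dt)))
}

#' Between-group variance of integrated measures
#'
#' Sample variance (divisor K - 1) of the K per-group integrated measures;
#' for the four sex-by-maternal-education groups the divisor is 3, for the
#' three evaluation scores it is 2.
#'
#' @param integrals numeric vector of per-group integrated measures
#'   (length at least 2).
#' @return the variance statistic.
#' @export
group_variance_statistic <- function(integrals) {
  K <- length(integrals)
  if (K < 2) stop("need at least two groups")
  sum((integrals - mean(integrals))^2) / (K - 1)
}

#' Permutation test for group effects on SCN evolution
#'
#' Tests whether the K sex-by-maternal-education groups differ in the
#' evolution of a threshold-averaged network measure.  For each of `Q`
#' permutations the group labels are randomly reassigned (preserving the
#' observed group sizes), the per-group SCN series is re-estimated, and
#' for every age \eqn{t_j} the between-group variance \eqn{T_j^{(q)}} of
#' the integrated measures \eqn{I_k^{(q)}(t_j)} is computed.  The
#' one-sided p-value at \eqn{t_j} is the proportion of permutations with
#' \eqn{T_j^{(q)} \ge T_j^{obs}}.  One set of permuted label vectors is
#' shared across all ages, and the mean growth curves are fit once on the
#' pooled sample (they do not depend on the labels).  No multiplicity
#' adjustment is applied across ages: each age's test already concerns the
#' whole trajectory from that age onward.
#'
#' @param data cohort table.
#' @param measure `"modularity"` or `"global_efficiency"`.
#' @param ages evaluation ages \eqn{t_1 < \ldots < t_N} (default 1..9).
#' @param thresholds threshold grid (default [default_thresholds()]).
#' @param Q number of permutations (5000 in full analyses; use a few
#'   hundred for exploration).
#' @param seed integer seed; results are reproducible given `(Q, seed)`
#'   and invariant to the order of permutations.
#' @param unit `"visit"` permutes observation labels (the procedure's
#'   definition, matching its i.i.d.-pairs working assumption); `"child"`
#'   permutes labels between children, keeping each child's visits
#'   together, as a robustness option under within-child dependence.
#' @param group a factor of length `nrow(data)`, a column name, or
#'   `"sex_mated"` (default) to derive the four standard groups.
#' @param kernel,bandwidth,mean_bandwidth,length_rule,restarts passed to
#'   the underlying fit and measure computation.
#' @param add_one use the (#+1)/(Q+1) p-value estimator instead of the
#'   plain proportion #/Q (off by default).
#' @param keep_perm keep the full matrix of permutation statistics.
#' @return an object of class `scn_permtest` with a per-age results table
#'   (`age`, `T_obs`, `p`, `n_perm_used`), the observed curves and
#'   integrals, the settings, and the number of discarded permutations.
#' @export
permutation_test_groups <- function(data, measure = "modularity",
                                    ages = 1:9,
                                    thresholds = default_thresholds(),
                                    Q = 200, seed = 1L,
                                    unit = c("visit", "child"),
                                    group = "sex_mated",
                                    kernel = "gaussian", bandwidth = NULL,
                                    mean_bandwidth = NULL,
                                    length_rule = "weight", restarts = 5L,
                                    add_one = FALSE, keep_perm = FALSE) {
  unit <- match.arg(unit)
  stopifnot(Q >= 1)
  fit <- frechet_scn(data, group = group, kernel = kernel,
                     bandwidth = bandwidth,
                     mean_bandwidth = mean_bandwidth)
  labels <- as.integer(fit$group)
  K <- nlevels(fit$group)
  n <- length(labels)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(seed, "group_permutations"))
  perm <- matrix(NA_integer_, n, Q + 1L)
  perm[, 1] <- labels
  if (unit == "visit") {
    for (q in seq_len(Q)) perm[, q + 1L] <- labels[sample.int(n)]
  } else {
    ids <- data$child_id
    if (is.null(ids)) stop("unit = 'child' needs a child_id column")
    uid <- unique(ids)
    child_lab <- labels[match(uid, ids)]
    for (q in seq_len(Q)) {
      shuffled <- child_lab[sample.int(length(uid))]
      perm[, q + 1L] <- shuffled[match(ids, uid)]
    }
  }
  scn_log("group permutation test: %s, Q = %d, %d visits, K = %d",
          measure, Q, n, K)
  cube <- cpp_perm_group_curves(
    fit$resid, fit$ages, perm, K, as.numeric(ages),
    fit$bandwidths$age_by_group, kernel_code(kernel),
    check_thresholds(thresholds), measure_code(measure),
    length_rule_code(length_rule),
    derive_seed(seed, "communities"), as.integer(restarts))
  assemble_permtest(cube, ages, measure, Q, seed, unit, length_rule,
                    scheme = "groups", fit = fit, add_one = add_one,
                    keep_perm = keep_perm,
                    group_sizes = as.numeric(table(fit$group)))
}

#' Permutation test for the association of a score with SCN evolution
#'
#' Analogue of [permutation_test_groups()] for a continuous cognitive
#' score: the bivariate (age, score) Frechet regression is evaluated at
#' `scores` (default 80/100/120, roughly the 10th/50th/90th percentile of
#' a Normal(100, 15^2) score), the integrated measure is computed per
#' score, and the statistic is the variance across the K = 3 score levels
#' (divisor 2).  Permutations shuffle the score column across
#' observations; the regression is refit for each permutation.
#'
#' @inheritParams permutation_test_groups
#' @param scores evaluation scores.
#' @param elc name of the score column.
#' @param elc_bandwidth score bandwidth (rule-of-thumb by default).
#' @return an `scn_permtest`, as for [permutation_test_groups()].
#' @export
permutation_test_elc <- function(data, measure = "global_efficiency",
                                 scores = c(80, 100, 120), ages = 1:9,
                                 thresholds = default_thresholds(),
                                 Q = 200, seed = 1L,
                                 unit = c("visit", "child"),
                                 elc = "elc", kernel = "gaussian",
                                 bandwidth = NULL, elc_bandwidth = NULL,
                                 mean_bandwidth = NULL,
                                 length_rule = "weight", restarts = 5L,
                                 add_one = FALSE, keep_perm = FALSE) {
  unit <- match.arg(unit)
  stopifnot(Q >= 1)
  fit <- frechet_scn(data, elc = elc, kernel = kernel,
                     bandwidth = bandwidth,
                     elc_bandwidth = elc_bandwidth,
                     mean_bandwidth = mean_bandwidth, scores = scores)
  n <- length(fit$ages)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(seed, "elc_permutations"))
  elcs <- matrix(NA_real_, n, Q + 1L)
  elcs[, 1] <- fit$elc
  if (unit == "visit") {
    for (q in seq_len(Q)) elcs[, q + 1L] <- fit$elc[sample.int(n)]
  } else {
    ids <- data$child_id
    if (is.null(ids)) stop("unit = 'child' needs a child_id column")
    uid <- unique(ids)
    child_elc <- fit$elc[match(uid, ids)]
    for (q in seq_len(Q)) {
      shuffled <- child_elc[sample.int(length(uid))]
      elcs[, q + 1L] <- shuffled[match(ids, uid)]
    }
  }
  scn_log("score permutation test: %s, Q = %d, %d visits, %d scores",
          measure, Q, n, length(scores))
  cube <- cpp_perm_elc_curves(
    fit$resid, fit$ages, elcs, as.numeric(ages), as.numeric(scores),
    fit$bandwidths$age, fit$bandwidths$elc, kernel_code(kernel),
    check_thresholds(thresholds), measure_code(measure),
    length_rule_code(length_rule),
    derive_seed(seed, "communities"), as.integer(restarts))
  assemble_permtest(cube, ages, measure, Q, seed, unit, length_rule,
                    scheme = "elc", fit = fit, add_one = add_one,
                    keep_perm = keep_perm, scores = scores)
}

# shared tail of the two tests: curves cube (K x N x (Q+1)) -> integrals,
# variance statistics, p-values; failed permutations are discarded (and
# counted), a failed observed run is an error
assemble_permtest <- function(cube, ages, measure, Q, seed, unit,
                              length_rule, scheme, fit, add_one,
                              keep_perm, group_sizes = NULL,
                              scores = NULL) {
  K <- dim(cube)[1]
  N <- dim(cube)[2]
  P <- dim(cube)[3]
  ages <- as.numeric(ages)
  stat_for <- function(p) {
    v <- cube[, , p, drop = FALSE]
    if (any(!is.finite(v))) return(NULL)
    I <- t(apply(matrix(v, K, N), 1, integrated_measures_all,
                 ages = ages))
    if (N == 1) I <- matrix(I, K, 1)
    apply(I, 2, group_variance_statistic)
  }
  T_obs <- stat_for(1)
  if (is.null(T_obs))
    stop("the observed measure curves could not be estimated; increase ",
         "the bandwidth or move evaluation ages inward")
  Tperm <- matrix(NA_real_, Q, N)
  discarded <- 0L
  for (q in seq_len(P - 1L)) {
    s <- stat_for(q + 1L)
    if (is.null(s)) discarded <- discarded + 1L else Tperm[q, ] <- s
  }
  if (discarded > 0)
    scn_log("discarded %d of %d permutations (degenerate cells)",
            discarded, Q)
  keep <- !is.na(Tperm[, 1])
  used <- sum(keep)
  if (used == 0) stop("all permutations failed")
  p <- vapply(seq_len(N), function(j) {
    ge <- sum(Tperm[keep, j] >= T_obs[j])
    if (add_one) (ge + 1) / (used + 1) else ge / used
  }, numeric(1))
  obs_curves <- matrix(cube[, , 1], K, N)
  rownames(obs_curves) <- if (!is.null(scores)) sprintf("elc=%g", scores)
                          else levels(fit$group)
  colnames(obs_curves) <- format(ages)
  structure(list(
    results = data.frame(age = ages, T_obs = T_obs, p = p,
                         n_perm_used = used),
    observed_curves = obs_curves,
    observed_integrals = t(apply(obs_curves, 1, integrated_measures_all,
                                 ages = ages)),
    perm_stats = if (keep_perm) Tperm[keep, , drop = FALSE] else NULL,
    perm_quantiles = apply(Tperm[keep, , drop = FALSE], 2, quantile,
                           probs = c(0.5, 0.9, 0.95, 0.99), names = TRUE),
    discarded = discarded,
    settings = list(measure = measure, scheme = scheme, ages = ages,
                    Q = Q, seed = seed, unit = unit,
                    length_rule = length_rule,
                    add_one = add_one,
                    group_sizes = group_sizes, scores = scores,
                    bandwidths = fit$bandwidths,
                    kernel = fit$kernel$family)),
    class = "scn_permtest")
}

#' @export
print.scn_permtest <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Permutation test on integrated %s trajectories (%s scheme)\n",
    s$measure, s$scheme))
  cat(sprintf("  Q = %d permutations (%d used), unit = %s, seed = %d\n",
              s$Q, x$results$n_perm_used[1], s$unit, s$seed))
  tab <- x$results
  tab$T_obs <- signif(tab$T_obs, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
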