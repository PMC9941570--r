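#' Community detection on a weighted SCN
#'
#' Finds a node partition with (near-)maximal weighted modularity.  For
#' networks with at most 8 nodes the maximum is found exactly by
#' enumerating all set partitions; larger networks use a seeded multilevel
#' (Louvain-style) heuristic with restarts, keeping the best modularity
#' found.  Isolated nodes may form their own module.
#'
#' @param adj adjacency matrix (e.g. from [threshold_network()]).
#' @param method `"auto"` (exact up to 8 nodes, multilevel above),
#'   `"exact"`, or `"multilevel"`.
#' @param seed integer seed for the multilevel heuristic (ignored by the
#'   exact search).
#' @param restarts number of multilevel restarts (best result kept).
#' @return an object of class `scn_partition` with `membership` (integer
#'   labels, contiguous from 1), `n_modules`, `modularity`, and `method`.
#' @export
detect_communities <- function(adj, method = c("auto", "exact",
                                               "multilevel"),
                               seed = 1L, restarts = 5L) {
  method <- match.arg(method)
  a <- check_adjacency(adj)
  m <- nrow(a)
  if (m < 1) stop("empty graph: no nodes")
  if (method == "exact" && m > 8)
    stop("exact partition enumeration is limited to 8 nodes")
  use_exact <- switch(method, auto = m <= 8, exact = TRUE,
                      multilevel = FALSE)
  if (sum(a) <= 0) {
    warning("network has no edges; single-module partition returned")
    part <- list(membership = rep(1L, m), modularity = 0,
                 exact = TRUE)
  } else if (use_exact) {
    part <- cpp_best_partition(a, as.integer(seed), as.integer(restarts))
  } else {
    part <- cpp_best_partition_multilevel(a, as.integer(seed),
                                          as.integer(restarts))
  }
  structure(list(membership = as.integer(part$membership),
                 n_modules = max(as.integer(part$membership)),
                 modularity = as.numeric(part$modularity),
                 method = if (isTRUE(part$exact)) "exact" else "multilevel"),
            class = "scn_partition")
}

#' @export
print.scn_partition <- function(x, ...) {
  cat(sprintf("<scn_partition: %d modules, Q = %.4f (%s)>\n", x$n_modules,
              x$modularity, x$method))
  invisible(x)
}

#' Weighted modularity of a partition
#'
#' \deqn{Q = \frac{1}{s} \sum_{i,j=1}^m \left(a_{ij} -
#'   \frac{d_i d_j}{s}\right) \delta_{m_i, m_j},}
#' with \eqn{s = \sum_{ij} a_{ij}} the total weight (each undirected edge
#' counted twice by the double sum) and \eqn{d_i} the weighted degree.  A
#' single-module partition always gives `Q = 0`; an edgeless network is
#' defined to have `Q = 0` (with a warning), since the double sum is empty.
#'
#' @param adj adjacency matrix.
#' @param partition an `scn_partition` or an integer membership vector.
#' @return modularity score in \eqn{[-1, 1]}.
#' @export
modularity <- function(adj, partition) {
  a <- check_adjacency(adj)
  memb <- if (inherits(partition, "scn_partition")) partition$membership
          else as.integer(partition)
  stopifnot(length(memb) == nrow(a))
  s <- sum(a)
  if (s <= 0) {
    warning("network has no edges; modularity defined as 0")
    return(0)
  }
  d <- rowSums(a)
  same <- outer(memb, memb, "==")
  sum((a - tcrossprod(d) / s)[same]) / s
}

#' Global efficiency of a weighted SCN
#'
#' \deqn{E = \frac{1}{m} \sum_i \frac{\sum_{j \ne i} l_{ij}^{-1}}{m - 1},}
#' the mean inverse weighted shortest-path length; disconnected pairs have
#' \eqn{l_{ij} = \infty} and contribute 0.  The default `length_rule`
#' `"weight"` takes each edge's length to be its weight, so a path's length
#' is the sum of the correlation weights along it; `"inverse"` uses
#' reciprocal weights (the convention in which stronger edges are shorter).
#' The rule in use is recorded in measure tables.
#'
#' @param adj adjacency matrix (at least 2 nodes).
#' @param length_rule `"weight"` (default) or `"inverse"`.
#' @return efficiency score, nonnegative.
#' @export
global_efficiency <- function(adj, length_rule = c("weight", "inverse")) {
  a <- check_adjacency(adj)
  if (nrow(a) < 2) stop("global efficiency needs at least 2 nodes")
  cpp_global_efficiency(a, length_rule_code(length_rule))
}

#' Average a network measure over the threshold grid
#'
#' The single summary used for inference: the arithmetic mean of the
#' measure over the threshold grid (on an equispaced grid this equals the
#' area under the measure-vs-threshold curve up to a constant factor).
#'
#' @param values numeric measure values, one per grid threshold; if named,
#'   names must match the grid.
#' @param grid the threshold grid.
#' @return the threshold-averaged measure.
#' @export
average_over_thresholds <- function(values, grid = default_thresholds()) {
  grid <- check_thresholds(grid)
  if (!is.null(names(values))) {
    key <- format(grid)
    missing <- setdiff(key, names(values))
    if (length(missing))
      stop("no measure value for threshold ", paste(missing,
                                                    collapse = ", "))
    values <- values[key]
  }
  if (length(values) != length(grid))
    stop(sprintf("expected %d values (one per threshold), got %d",
                 length(grid), length(values)))
  if (any(!is.finite(values))) {
    bad <- grid[!is.finite(values)]
    stop("non-finite measure value at threshold ",
         paste(format(bad), collapse = ", "))
  }
  # sequential summation (not mean()) so results are bitwise identical to
  # the compiled permutation engine
  Reduce(`+`, as.list(as.numeric(values))) / length(values)
}

#' Threshold-averaged measure curves for a fitted model
#'
#' Computes, for each group (or evaluation score) and each age, the chosen
#' network measure averaged over the threshold grid.  This uses the same
#' compiled path as the permutation engines, so observed curves here are
#' bitwise identical to the observed run inside
#' [permutation_test_groups()] / [permutation_test_elc()].
#'
#' @param object a fitted [frechet_scn()] model.
#' @param measure `"modularity"` or `"global_efficiency"`.
#' @param ages evaluation ages.
#' @param thresholds threshold grid.
#' @param scores evaluation scores (bivariate fits only).
#' @param length_rule shortest-path length rule, see [global_efficiency()].
#' @param seed,restarts community-detection settings (networks with more
#'   than 8 nodes only; smaller networks are solved exactly).
#' @return data frame with columns `group`, `age`, `value` plus metadata
#'   columns `measure`, `length_rule`, `community_seed`.
#' @export
scn_measure_curves <- function(object, measure = "modularity", ages = 1:9,
                               thresholds = default_thresholds(),
                               scores = NULL,
                               length_rule = "weight", seed = 1L,
                               restarts = 5L) {
  stopifnot(inherits(object, "frechet_scn"))
  thresholds <- check_thresholds(thresholds)
  mcode <- measure_code(measure)
  rcode <- length_rule_code(length_rule)
  if (!is.null(object$elc)) {
    if (is.null(scores)) scores <- object$scores
    cube <- cpp_perm_elc_curves(object$resid, object$ages,
                                matrix(object$elc, ncol = 1),
                                as.numeric(ages), as.numeric(scores),
                                object$bandwidths$age,
                                object$bandwidths$elc,
                                kernel_code(object$kernel), thresholds,
                                mcode, rcode, as.integer(seed),
                                as.integer(restarts))
    groups <- sprintf("elc=%g", scores)
  } else {
    labels <- if (is.null(object$group)) rep(1L, length(object$ages))
              else as.integer(object$group)
    K <- max(labels)
    cube <- cpp_perm_group_curves(object$resid, object$ages,
                                  matrix(labels, ncol = 1), K,
                                  as.numeric(ages),
                                  object$bandwidths$age_by_group,
                                  kernel_code(object$kernel), thresholds,
                                  mcode, rcode, as.integer(seed),
                                  as.integer(restarts))
    groups <- if (is.null(object$group)) "all" else levels(object$group)
  }
  vals <- cube[, , 1, drop = FALSE]
  out <- data.frame(
    group = rep(groups, times = length(ages)),
    age = rep(as.numeric(ages), each = length(groups)),
    value = as.numeric(vals),
    measure = measure,
    length_rule = match.arg(length_rule, c("weight", "inverse")),
    community_seed = as.integer(seed),
    stringsAsFactors = FALSE)
  if (any(!is.finite(out$value)))
    stop("measure curve could not be estimated at some (group, age) cell; ",
         "increase the bandwidth or move evaluation ages inward")
  out
}

check_adjacency <- function(adj) {
  a <- as.matrix(adj)
  if (nrow(a) != ncol(a)) stop("adjacency matrix must be square")
  if (nrow(a) == 0) stop("empty graph: no nodes")
  if (!all(is.finite(a))) stop("adjacency matrix has non-finite entries")
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency matrix must be symmetric")
  if (any(a < 0)) stop("adjacency weights must be nonnegative")
  a
}
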