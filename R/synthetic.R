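#' Configuration of the synthetic accelerated-longitudinal cohort
#'
#' Builds a validated configuration for [generate_cohort()].  Defaults
#' emulate a community cohort of healthy children: 554 children, visit
#' counts concentrated on a single visit (at most 8), ages 0.17 to 10
#' years, about 62% of mothers with a bachelor's degree, and a cognitive
#' score (ELC) distributed as Normal(100, 15^2).  Regional volumes follow
#' saturating-exponential growth curves (about 80% of the adult level by
#' age 2) with a two-block ("non-cortical" vs "cortical") correlation
#' structure whose strength changes with age and covariates.
#'
#' The default correlation dynamics give downstream tests a directional
#' truth: within-block correlation rises with age, is higher under high
#' maternal education, and falls with higher ELC scores.  The parametric
#' form is
#' \deqn{\rho_w(t, g) = b + s \frac{t - lo}{hi - lo}
#'   + \gamma_{med} 1\{g \mathrm{high}\} + \gamma_{elc} \frac{z - 100}{15}
#'   + \beta \max(0, t - t_0) / (hi - t_0) 1\{g = g^*\},}
#' clamped to (-0.99, 0.99), and similarly (without group terms) for the
#' between-block correlation.  Arbitrary functions `rho_within(t, g)` and
#' `rho_between(t, g)` may be supplied instead (such configurations cannot
#' be serialized to JSON).  Positive definiteness of the implied
#' correlation matrix is checked on a dense age grid at construction.
#'
#' @param n_children number of children.
#' @param m_rois number of regions (default 20; the motivating analyses
#'   use 91).
#' @param age_range admissible visit ages in years.
#' @param visits_pmf probability vector over 1..8 visits per child; the
#'   default mirrors an accelerated-longitudinal visit distribution where
#'   most children contribute one visit.
#' @param p_male probability that a child is male.
#' @param p_high_mated probability of high maternal education (bachelor's
#'   degree or above, i.e. ordinal level 6 or 7).
#' @param elc_mean,elc_sd mean and SD of the cognitive score.
#' @param block_split indices of the first ("non-cortical") block; the
#'   remaining ROIs form the "cortical" block.  Default: the first 30% of
#'   regions.
#' @param rho named list of correlation-dynamic parameters:
#'   `within_base`, `within_slope`, `mated_gain`, `elc_gain`,
#'   `between_base`, `between_slope`, `boost_group` (a label like
#'   `"M_high"` or `NULL`), `boost_after`, `boost_amount`.
#' @param rho_within,rho_between optional functions `(t, g)` overriding the
#'   parametric dynamics; `g` is a list with `sex`, `mated` (`"low"` /
#'   `"high"`), and `elc`.
#' @param growth list with `c` and `k` of the growth law
#'   `adult * (1 - c * exp(-k t))`.
#' @param adult_volumes per-ROI adult volume levels (default: log-spaced
#'   between 5 and 50 volume units).
#' @param cv coefficient of variation of volumes around the mean curve.
#' @param child_effect_sd SD of an optional log-normal child-level random
#'   volume factor shared across a child's visits (0 disables it; the
#'   estimator treats visits as independent, so this knob exists to probe
#'   robustness against that working assumption).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_children = 554L,
                             m_rois = 20L,
                             age_range = c(0.17, 10),
                             visits_pmf = default_visits_pmf(),
                             p_male = 309 / 554,
                             p_high_mated = 0.62,
                             elc_mean = 100, elc_sd = 15,
                             block_split = NULL,
                             rho = list(),
                             rho_within = NULL, rho_between = NULL,
                             growth = list(c = 0.7, k = 0.7),
                             adult_volumes = NULL,
                             cv = 0.12,
                             child_effect_sd = 0,
                             seed = 1L) {
  stopifnot(n_children >= 1, m_rois >= 2, length(age_range) == 2,
            age_range[1] < age_range[2], p_male >= 0, p_male <= 1,
            p_high_mated >= 0, p_high_mated <= 1, elc_sd > 0, cv > 0,
            child_effect_sd >= 0)
  visits_pmf <- as.numeric(visits_pmf)
  if (length(visits_pmf) != 8 || any(visits_pmf < 0) ||
      abs(sum(visits_pmf) - 1) > 1e-12)
    stop("visits_pmf must be 8 nonnegative probabilities summing to 1 ",
         "(within 1e-12)")
  if (is.null(block_split)) block_split <- seq_len(ceiling(0.3 * m_rois))
  block_split <- sort(unique(as.integer(block_split)))
  if (length(block_split) < 1 || length(block_split) >= m_rois ||
      any(block_split < 1) || any(block_split > m_rois))
    stop("block_split must be a nonempty proper subset of 1..m_rois")
  rho_defaults <- list(within_base = 0.35, within_slope = 0.30,
                       mated_gain = 0.10, elc_gain = -0.10,
                       between_base = 0.10, between_slope = 0.10,
                       boost_group = NULL, boost_after = 5,
                       boost_amount = 0)
  rho <- utils::modifyList(rho_defaults, rho)
  if (is.null(adult_volumes))
    adult_volumes <- exp(seq(log(5), log(50), length.out = m_rois))
  stopifnot(length(adult_volumes) == m_rois, all(adult_volumes > 0),
            growth$c > 0, growth$c < 1, growth$k > 0)
  cfg <- structure(list(
    n_children = as.integer(n_children), m_rois = as.integer(m_rois),
    age_range = as.numeric(age_range), visits_pmf = visits_pmf,
    p_male = p_male, p_high_mated = p_high_mated,
    elc_mean = elc_mean, elc_sd = elc_sd,
    block_split = block_split, rho = rho,
    rho_within = rho_within, rho_between = rho_between,
    growth = growth, adult_volumes = as.numeric(adult_volumes), cv = cv,
    child_effect_sd = child_effect_sd, seed = as.integer(seed)),
    class = "synthetic_config")
  check_pd_on_grid(cfg)
  cfg
}

#' Default visits-per-child distribution
#'
#' Empirical distribution of visit counts (1 to 8) in a 554-child
#' accelerated-longitudinal cohort; most children contribute one visit.
#'
#' @return probability vector of length 8.
#' @export
default_visits_pmf <- function() {
  counts <- c(142 + 163, 60 + 71, 14 + 42, 15 + 19, 11 + 6, 3 + 6, 0 + 1,
              0 + 1)
  counts / sum(counts)
}

# evaluate the within-/between-block correlation dynamics at (t, g)
rho_fun <- function(cfg, which = c("within", "between")) {
  which <- match.arg(which)
  user <- if (which == "within") cfg$rho_within else cfg$rho_between
  if (!is.null(user)) return(user)
  p <- cfg$rho
  lo <- cfg$age_range[1]; hi <- cfg$age_range[2]
  function(t, g) {
    frac <- (t - lo) / (hi - lo)
    if (which == "within") {
      r <- p$within_base + p$within_slope * frac
      if (identical(g$mated, "high")) r <- r + p$mated_gain
      if (!is.null(g$elc) && is.finite(g$elc))
        r <- r + p$elc_gain * (g$elc - cfg$elc_mean) / cfg$elc_sd
      if (!is.null(p$boost_group) &&
          identical(paste0(g$sex, "_", g$mated), p$boost_group))
        r <- r + p$boost_amount * pmax(0, t - p$boost_after) /
          (hi - p$boost_after)
    } else {
      r <- p$between_base + p$between_slope * frac
    }
    pmin(pmax(r, -0.99), 0.99)
  }
}

#' True correlation matrix implied by a synthetic configuration
#'
#' The exact block-structured correlation matrix \eqn{R(t, g)} used when
#' drawing volumes: unit diagonal, within-block entries
#' \eqn{\rho_w(t, g)}, between-block entries \eqn{\rho_b(t, g)}.
#'
#' @param config a [synthetic_config()].
#' @param t age in years (inside `age_range`).
#' @param g group / covariate list with any of `sex`, `mated`, `elc`;
#'   missing entries default to a female child with high maternal
#'   education and the mean ELC score.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
true_correlation <- function(config, t,
                             g = list(sex = "F", mated = "high",
                                      elc = NULL)) {
  stopifnot(inherits(config, "synthetic_config"))
  if (t < config$age_range[1] || t > config$age_range[2])
    stop(sprintf("age %s outside the configured age range [%s, %s]",
                 format(t), format(config$age_range[1]),
                 format(config$age_range[2])))
  g <- utils::modifyList(list(sex = "F", mated = "high",
                              elc = config$elc_mean), g)
  m <- config$m_rois
  in1 <- seq_len(m) %in% config$block_split
  rw <- rho_fun(config, "within")(t, g)
  rb <- rho_fun(config, "between")(t, g)
  R <- matrix(NA_real_, m, m)
  same <- outer(in1, in1, "==")
  R[same] <- rw
  R[!same] <- rb
  diag(R) <- 1
  rownames(R) <- colnames(R) <- sprintf("roi_%03d", seq_len(m))
  R
}

# positive definiteness of the implied correlation over a dense age grid
# and representative covariate corners; errors name the failing age
check_pd_on_grid <- function(cfg, n_grid = 40) {
  ts <- seq(cfg$age_range[1], cfg$age_range[2], length.out = n_grid)
  corners <- list(
    list(sex = "F", mated = "low", elc = cfg$elc_mean - 2 * cfg$elc_sd),
    list(sex = "F", mated = "high", elc = cfg$elc_mean - 2 * cfg$elc_sd),
    list(sex = "M", mated = "low", elc = cfg$elc_mean + 2 * cfg$elc_sd),
    list(sex = "M", mated = "high", elc = cfg$elc_mean + 2 * cfg$elc_sd))
  if (!is.null(cfg$rho$boost_group)) {
    sx <- sub("_.*", "", cfg$rho$boost_group)
    md <- sub(".*_", "", cfg$rho$boost_group)
    corners <- c(corners, list(list(sex = sx, mated = md,
                                    elc = cfg$elc_mean)))
  }
  for (t in ts) {
    for (g in corners) {
      R <- true_correlation(cfg, t, g)
      ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
      if (ev <= 1e-8)
        stop(sprintf(paste0("implied correlation matrix is not positive ",
                            "definite at age %.3g (min eigenvalue %.3g); ",
                            "weaken the correlation dynamics"), t, ev))
    }
  }
  invisible(TRUE)
}

# per-ROI mean and SD curves
mean_curve_at <- function(cfg, t) {
  cfg$adult_volumes * (1 - cfg$growth$c * exp(-cfg$growth$k * t))
}
sd_curve_at <- function(cfg, t) cfg$cv * mean_curve_at(cfg, t)

#' Generate a synthetic accelerated-longitudinal cohort
#'
#' Draws children (sex, maternal education, ELC score, visit count), visit
#' ages, and per-visit volume vectors from the multivariate normal with the
#' configured age- and covariate-dependent mean and covariance.  Fully
#' deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a `data.frame` of class `cohort_table` with one row per visit:
#'   `child_id`, `age`, `sex` (`"F"`/`"M"`), `mated` (ordinal 1-7), `elc`,
#'   and `roi_001` ... volume columns.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  m <- config$m_rois
  lo <- config$age_range[1]; hi <- config$age_range[2]
  rows <- vector("list", config$n_children)
  for (i in seq_len(config$n_children)) {
    sex <- if (runif(1) < config$p_male) "M" else "F"
    high <- runif(1) < config$p_high_mated
    mated <- if (high) sample(6:7, 1, prob = c(0.6, 0.4))
             else sample(1:5, 1, prob = c(0.02, 0.05, 0.13, 0.40, 0.40))
    elc <- rnorm(1, config$elc_mean, config$elc_sd)
    nv <- sample.int(8, 1, prob = config$visits_pmf)
    ages <- sort(lo + (hi - lo) * runif(nv))
    fac <- if (config$child_effect_sd > 0)
      exp(rnorm(1, 0, config$child_effect_sd)) else 1
    g <- list(sex = sex, mated = if (high) "high" else "low", elc = elc)
    vols <- matrix(NA_real_, nv, m)
    for (v in seq_len(nv)) {
      R <- true_correlation(config, ages[v], g)
      sdv <- sd_curve_at(config, ages[v])
      L <- chol(R)
      z <- rnorm(m)
      vols[v, ] <- fac * (mean_curve_at(config, ages[v]) +
                            sdv * drop(crossprod(L, z)))
    }
    rows[[i]] <- data.frame(
      child_id = sprintf("C%04d", i), age = ages, sex = sex,
      mated = mated, elc = elc, vols,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:5)] <- sprintf("roi_%03d", seq_len(m))
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort table as CSV
#'
#' Long format, one row per visit, header
#' `child_id, age, sex, mated, elc, roi_001, ...`.  Numbers are written in
#' full precision so a write/read round trip is lossless.
#'
#' @param data a cohort table.
#' @param path file path.
#' @return `write_cohort` returns the path invisibly; `read_cohort`
#'   returns the `cohort_table`.
#' @export
write_cohort <- function(data, path) {
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("child_id", "age", "sex", "mated", "elc")
  missing <- setdiff(needed, names(out))
  if (length(missing))
    stop("cohort CSV is missing columns: ", paste(missing, collapse = ", "))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Serialize / restore a synthetic configuration
#'
#' Parametric configurations round-trip losslessly through JSON.
#' Configurations with user-supplied `rho_within` / `rho_between`
#' functions cannot be serialized and raise an error.
#'
#' @param config a [synthetic_config()].
#' @param path file path (`.json`).
#' @return `write_synthetic_config` returns the path invisibly;
#'   `read_synthetic_config` returns the restored, revalidated
#'   `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$rho_within) || !is.null(config$rho_between))
    stop("configurations with function-valued correlation dynamics ",
         "cannot be serialized")
  x <- unclass(config)
  x$rho_within <- NULL
  x$rho_between <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$rho)) {
    x$rho <- as.list(x$rho)
    if (length(x$rho$boost_group) == 0) x$rho$boost_group <- NULL
  }
  if (!is.null(x$growth)) x$growth <- as.list(x$growth)
  do.call(synthetic_config, x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    paste0("<synthetic_config: %d children, %d ROIs, ages [%g, %g], ",
           "seed %d>\n"),
    x$n_children, x$m_rois, x$age_range[1], x$age_range[2], x$seed))
  invisible(x)
}
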