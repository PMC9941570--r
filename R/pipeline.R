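#' Analysis configuration for the SCN pipeline
#'
#' A single, serializable object carrying everything the pipeline commands
#' need: where to read the cohort, where to write outputs, the synthetic
#' generator parameters (for [cmd_simulate()]), and the analysis settings.
#' Defaults follow the standard design: evaluation ages 1..9 years,
#' thresholds 0.60..0.90 in steps of 0.05, Q = 5000 permutations for full
#' analyses.  Every command writes the fully resolved configuration next
#' to its outputs, so a run can be reproduced from its output directory
#' alone.
#'
#' @param cohort_csv path of the cohort CSV (written by [cmd_simulate()],
#'   read by the analysis commands).
#' @param output_dir output directory (created if missing).
#' @param synthetic either a [synthetic_config()] or a named list of its
#'   arguments.
#' @param mode `"groups"` (sex by maternal education) or `"elc"`.
#' @param ages,thresholds,kernel,bandwidth,measures,length_rule,Q,unit,
#'   scores,restarts analysis settings; see
#'   [permutation_test_groups()] and [scn_measure_curves()].
#' @param seed run seed; all stage seeds are derived from it
#'   deterministically.
#' @return an object of class `scn_config`.
#' @export
scn_config <- function(cohort_csv = "cohort.csv", output_dir = ".",
                       synthetic = list(), mode = c("groups", "elc"),
                       ages = 1:9, thresholds = default_thresholds(),
                       kernel = "gaussian", bandwidth = NULL,
                       measures = c("modularity", "global_efficiency"),
                       length_rule = "weight", Q = 5000L,
                       unit = "visit", scores = c(80, 100, 120),
                       restarts = 5L, seed = 1L) {
  mode <- match.arg(mode)
  if (!inherits(synthetic, "synthetic_config"))
    synthetic <- do.call(synthetic_config, as.list(synthetic))
  measures <- match.arg(measures, c("modularity", "global_efficiency"),
                        several.ok = TRUE)
  structure(list(cohort_csv = cohort_csv, output_dir = output_dir,
                 synthetic = synthetic, mode = mode,
                 ages = as.numeric(ages),
                 thresholds = check_thresholds(thresholds),
                 kernel = kernel, bandwidth = bandwidth,
                 measures = measures, length_rule = length_rule,
                 Q = as.integer(Q), unit = unit,
                 scores = as.numeric(scores),
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "scn_config")
}

#' Serialize / restore an analysis configuration
#'
#' JSON round trip of an [scn_config()] (lossless for parametric
#' synthetic configurations).  YAML files can be read when the `yaml`
#' package is available.
#'
#' @param config an `scn_config`.
#' @param path file path (`.json`, or `.yaml`/`.yml` for reading).
#' @return `write_scn_config` returns the path invisibly;
#'   `read_scn_config` the restored `scn_config`.
#' @export
write_scn_config <- function(config, path) {
  stopifnot(inherits(config, "scn_config"))
  x <- unclass(config)
  x$synthetic <- unclass(x$synthetic)
  x$synthetic$rho_within <- NULL
  x$synthetic$rho_between <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_scn_config
#' @export
read_scn_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configurations needs the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(x$synthetic)) {
    x$synthetic <- as.list(x$synthetic)
    if (!is.null(x$synthetic$rho))
      x$synthetic$rho <- as.list(x$synthetic$rho)
    if (length(x$synthetic$rho$boost_group) == 0)
      x$synthetic$rho$boost_group <- NULL
    if (!is.null(x$synthetic$growth))
      x$synthetic$growth <- as.list(x$synthetic$growth)
  }
  if (!is.null(x$bandwidth) && length(x$bandwidth) == 0) x$bandwidth <- NULL
  do.call(scn_config, x)
}

resolve_out <- function(config, ...) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(config$output_dir, ...)
}

write_resolved_config <- function(config, suffix) {
  write_scn_config(config,
                   resolve_out(config,
                               sprintf("config_%s.json", suffix)))
}

#' Pipeline command: simulate a cohort
#'
#' Generates the configured synthetic cohort, writes it as CSV next to a
#' truth sidecar (the synthetic configuration, from which
#' [true_correlation()] reproduces the exact generating correlation at any
#' age), and records the resolved configuration.
#'
#' @param config an [scn_config()].
#' @return path of the cohort CSV, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "scn_config"))
  scn_log("simulate: %d children, %d ROIs, seed %d",
          config$synthetic$n_children, config$synthetic$m_rois,
          config$synthetic$seed)
  cohort <- generate_cohort(config$synthetic)
  path <- resolve_out(config, config$cohort_csv)
  write_cohort(cohort, path)
  write_synthetic_config(config$synthetic,
                         resolve_out(config, "truth_config.json"))
  write_resolved_config(config, "simulate")
  scn_log("simulate: wrote %d visits to %s", nrow(cohort), path)
  invisible(path)
}

#' Pipeline command: build SCNs and measure curves
#'
#' Reads the cohort, fits the model for the configured mode (four
#' sex-by-maternal-education groups, or three evaluation scores of the
#' bivariate fit), writes one adjacency-matrix CSV per (group, age,
#' threshold) cell, a manifest listing all cells, the ROI labels, and a
#' measure-curve table with per-threshold and threshold-averaged rows.
#'
#' @param config an [scn_config()].
#' @return the measure-curve data frame, invisibly.
#' @export
cmd_scn <- function(config) {
  stopifnot(inherits(config, "scn_config"))
  cohort <- read_cohort(resolve_out(config, config$cohort_csv))
  fit <- build_fit(config, cohort)
  series <- build_scn_series(fit, config$ages, config$thresholds,
                             scores = if (config$mode == "elc")
                               config$scores else NULL)
  scn_dir <- resolve_out(config, "scn")
  dir.create(scn_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(series$cells, function(cell) {
    fname <- sprintf("%s_age%s_theta%s.csv",
                     gsub("[^A-Za-z0-9=._-]", "-", cell$group),
                     fmt_num(cell$age), fmt_num(cell$theta))
    write_matrix_csv(cell$adjacency, file.path(scn_dir, fname),
                     series$rois)
    list(group = cell$group, age = cell$age, theta = cell$theta,
         file = file.path("scn", fname))
  })
  jsonlite::write_json(manifest, resolve_out(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(series$rois, resolve_out(config, "roi_labels.txt"))
  curves <- measure_table(fit, config)
  write_curves_csv(curves, resolve_out(config, "measure_curves.csv"))
  write_resolved_config(config, "scn")
  scn_log("scn: wrote %d adjacency matrices and %d curve rows",
          length(series$cells), nrow(curves))
  invisible(curves)
}

build_fit <- function(config, cohort) {
  if (config$mode == "elc")
    frechet_scn(cohort, elc = "elc", kernel = config$kernel,
                bandwidth = config$bandwidth, scores = config$scores)
  else
    frechet_scn(cohort, group = "sex_mated", kernel = config$kernel,
                bandwidth = config$bandwidth)
}

# per-threshold and threshold-averaged measure rows for every measure
measure_table <- function(fit, config) {
  out <- list()
  for (ms in config$measures) {
    avg <- scn_measure_curves(
      fit, ms, config$ages, config$thresholds,
      scores = if (config$mode == "elc") config$scores else NULL,
      length_rule = config$length_rule,
      seed = derive_seed(config$seed, "communities"),
      restarts = config$restarts)
    for (th in config$thresholds) {
      per <- scn_measure_curves(
        fit, ms, config$ages, th,
        scores = if (config$mode == "elc") config$scores else NULL,
        length_rule = config$length_rule,
        seed = derive_seed(config$seed, "communities"),
        restarts = config$restarts)
      per$theta <- fmt_num(th)
      out[[length(out) + 1]] <- per
    }
    avg$theta <- "avg"
    out[[length(out) + 1]] <- avg
  }
  do.call(rbind, out)[, c("group", "age", "theta", "measure", "value",
                          "length_rule", "community_seed")]
}

write_curves_csv <- function(curves, path) {
  df <- curves
  df$age <- fmt_num(df$age)
  df$value <- fmt_num(df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline command: permutation tests
#'
#' Runs the configured permutation test (group scheme or score scheme) at
#' all evaluation ages for every configured measure, and writes a results
#' JSON with the settings block, per-age records (observed statistic,
#' p-value, permutation quantiles), and the discarded-permutation count.
#'
#' @param config an [scn_config()].
#' @return named list of `scn_permtest` objects (one per measure),
#'   invisibly.
#' @export
cmd_test <- function(config) {
  stopifnot(inherits(config, "scn_config"))
  cohort <- read_cohort(resolve_out(config, config$cohort_csv))
  tests <- list()
  for (ms in config$measures) {
    tests[[ms]] <- if (config$mode == "elc")
      permutation_test_elc(cohort, measure = ms, scores = config$scores,
                           ages = config$ages,
                           thresholds = config$thresholds, Q = config$Q,
                           seed = config$seed, unit = config$unit,
                           kernel = config$kernel,
                           bandwidth = config$bandwidth,
                           length_rule = config$length_rule,
                           restarts = config$restarts)
    else
      permutation_test_groups(cohort, measure = ms, ages = config$ages,
                              thresholds = config$thresholds,
                              Q = config$Q, seed = config$seed,
                              unit = config$unit, kernel = config$kernel,
                              bandwidth = config$bandwidth,
                              length_rule = config$length_rule,
                              restarts = config$restarts)
    scn_log("test (%s): min p = %s, %d permutations discarded", ms,
            fmt_num(min(tests[[ms]]$results$p)), tests[[ms]]$discarded)
  }
  json <- lapply(tests, function(tt) {
    list(settings = tt$settings[c("measure", "scheme", "ages", "Q",
                                  "seed", "unit", "length_rule",
                                  "kernel")],
         bandwidths = tt$settings$bandwidths,
         discarded = tt$discarded,
         results = lapply(seq_len(nrow(tt$results)), function(i) {
           list(age = tt$results$age[i], T_obs = tt$results$T_obs[i],
                p = tt$results$p[i],
                n_perm_used = tt$results$n_perm_used[i],
                perm_quantiles = as.list(tt$perm_quantiles[, i]))
         }))
  })
  jsonlite::write_json(json, resolve_out(config, "test_results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_resolved_config(config, "test")
  invisible(tests)
}

#' @export
print.scn_config <- function(x, ...) {
  cat(sprintf(
    "<scn_config: mode = %s, ages %s, %d thresholds, Q = %d, seed = %d>\n",
    x$mode, paste(range(x$ages), collapse = "-"), length(x$thresholds),
    x$Q, x$seed))
  invisible(x)
}
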