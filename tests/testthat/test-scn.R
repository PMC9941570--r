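# covariance -> correlation -> thresholded network

test_that("cov_to_corr standardizes exactly and clips to [-1, 1]", {
  # 2/sqrt(4*1) = 1
  S <- matrix(c(4, 2, 2, 1), 2)
  expect_equal(unclass(cov_to_corr(S)), matrix(1, 2, 2),
               ignore_attr = TRUE)
  expect_equal(unclass(cov_to_corr(diag(3))), diag(3),
               ignore_attr = TRUE)
  set.seed(41)
  v <- rnorm(4)
  S2 <- tcrossprod(v) + diag(0.5, 4)
  R <- cov_to_corr(S2)
  expect_equal(diag(unclass(R)), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(R >= -1 & R <= 1))
  expect_equal(unclass(R), t(unclass(R)))
})

test_that("degenerate variances are reported by ROI name", {
  S <- diag(c(1, 0, 2))
  rownames(S) <- colnames(S) <- c("a", "b", "c")
  expect_error(cov_to_corr(S), "ROI b")
})

test_that("thresholding keeps values, removes the rest, zeroes the diagonal", {
  R <- matrix(c(1, 0.85, -0.9, 0.85, 1, 0.79, -0.9, 0.79, 1), 3)
  A <- threshold_network(R, 0.8)
  expect_equal(A[1, 2], 0.85)   # keep branch retains the value
  expect_equal(A[2, 3], 0)      # below threshold
  expect_equal(A[1, 3], 0)      # negative correlations always removed
  expect_equal(diag(unclass(A)), rep(0, 3), ignore_attr = TRUE)
  expect_error(threshold_network(R, 1.2), "theta")
})

test_that("edge sets are nested in the threshold and values are unscaled", {
  set.seed(42)
  v <- matrix(rnorm(30), 5)
  R <- cov_to_corr(tcrossprod(v) / 6 + diag(0.1, 5))
  grid <- default_thresholds()
  prev <- NULL
  for (th in rev(grid)) {
    A <- threshold_network(R, th)
    nz <- which(unclass(A) != 0)
    expect_equal(unclass(A)[nz], unclass(R)[nz])  # exact values kept
    if (!is.null(prev)) expect_true(all(prev %in% nz))  # nesting
    prev <- nz
  }
})

test_that("an SCN series enumerates the full (group, age, theta) grid", {
  cfg <- quick_config(n_children = 120, m_rois = 6, seed = 10)
  coh <- generate_cohort(cfg)
  fit <- frechet_scn(coh, group = "sex_mated")
  series <- build_scn_series(fit, ages = c(3, 6), thresholds = c(0.6, 0.8))
  expect_length(series$cells, 4 * 2 * 2)
  # composition: a single cell equals calling the stages by hand
  R <- predict(fit, ages = 6, groups = "F_high")
  expect_identical(unclass(series_cell(series, 6, 0.8, "F_high")),
                   unclass(threshold_network(R, 0.8)))
  expect_error(series_cell(series, 4.5, 0.8, "F_high"), "no cell")
  expect_error(build_scn_series(fit, ages = c(0.05)), "inside")
})

test_that("strong within-block truth shows up as within-block edge density", {
  cfg <- synthetic_config(
    n_children = 800, m_rois = 8, seed = 11,
    visits_pmf = c(1, rep(0, 7)),
    rho = list(within_base = 0.55, within_slope = 0.35, mated_gain = 0,
               elc_gain = 0, between_base = 0.05, between_slope = 0.05))
  coh <- generate_cohort(cfg)
  fit <- frechet_scn(coh)
  A <- unclass(predict(fit, ages = 8, what = "adjacency", theta = 0.8))
  blk <- seq_len(8) %in% cfg$block_split
  same <- outer(blk, blk, "==") & !diag(TRUE, 8)
  dens_within <- mean(A[same] > 0)
  dens_between <- mean(A[!same] > 0)
  expect_gt(dens_within, dens_between)
})
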