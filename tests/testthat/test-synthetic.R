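# synthetic cohort generator: determinism, marginals, implied truth

test_that("generation is deterministic given the seed", {
  cfg <- quick_config(n_children = 50, m_rois = 5, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- quick_config(n_children = 50, m_rois = 5, seed = 100)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("visit counts follow the configured distribution", {
  cfg <- synthetic_config(n_children = 10, m_rois = 4,
                          visits_pmf = c(1, rep(0, 7)), seed = 1)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 10)
  # every child appears between 1 and 8 times under the default pmf
  cfg2 <- synthetic_config(n_children = 300, m_rois = 4, seed = 2)
  counts <- table(generate_cohort(cfg2)$child_id)
  expect_true(all(counts >= 1 & counts <= 8))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(visits_pmf = rep(0.2, 8)), "summing to 1")
  expect_error(synthetic_config(m_rois = 6, block_split = 1:6),
               "proper subset")
  # overly strong between-block coupling -> not positive definite, with
  # the failing age named
  expect_error(
    synthetic_config(m_rois = 6,
                     rho = list(within_base = 0.2, within_slope = 0,
                                mated_gain = 0, elc_gain = 0,
                                between_base = 0.9, between_slope = 0)),
    "not positive definite at age")
})

test_that("true_correlation reflects the block construction", {
  cfg <- synthetic_config(
    m_rois = 6, block_split = 1:3,
    rho = list(within_base = 0.4, within_slope = 0, mated_gain = 0,
               elc_gain = 0, between_base = 0.4, between_slope = 0))
  R <- true_correlation(cfg, 5)
  # rho_within = rho_between -> compound symmetry
  expect_equal(unclass(R), 0.4 + diag(0.6, 6), ignore_attr = TRUE)
  expect_equal(diag(R), rep(1, 6), ignore_attr = TRUE)
  cfg2 <- synthetic_config(
    m_rois = 6, block_split = 1:3,
    rho = list(within_base = 0.5, within_slope = 0, mated_gain = 0,
               elc_gain = 0, between_base = 0, between_slope = 0))
  R2 <- unclass(true_correlation(cfg2, 5))
  expect_true(all(R2[1:3, 4:6] == 0))  # block diagonal
  expect_error(true_correlation(cfg2, 12), "outside")
})

test_that("high maternal education frequency matches the configuration", {
  cfg <- synthetic_config(n_children = 2000, m_rois = 3, seed = 4,
                          visits_pmf = c(1, rep(0, 7)))
  coh <- generate_cohort(cfg)
  expect_lt(abs(mean(coh$mated >= 6) - 0.62), 0.03)
})

test_that("zero correlation dynamics yield uncorrelated volumes", {
  cfg <- synthetic_config(
    n_children = 4000, m_rois = 4, seed = 5,
    visits_pmf = c(1, rep(0, 7)),
    rho = list(within_base = 0, within_slope = 0, mated_gain = 0,
               elc_gain = 0, between_base = 0, between_slope = 0))
  coh <- generate_cohort(cfg)
  win <- coh[abs(coh$age - 5) <= 0.25, ]
  R <- cor(as.matrix(win[, grep("^roi", names(coh))]))
  se <- 1 / sqrt(nrow(win) - 3)  # Fisher-z standard error
  off <- R[upper.tri(R)]
  expect_true(all(abs(atanh(off)) < 3 * se))
})

test_that("windowed empirical covariance converges to the truth", {
  # mean Frobenius error of the +-0.25y windowed covariance at age 5
  # must shrink as the cohort grows
  err_for <- function(n_children, seed) {
    cfg <- synthetic_config(
      n_children = n_children, m_rois = 5, seed = seed,
      visits_pmf = c(1, rep(0, 7)), p_high_mated = 1,
      rho = list(mated_gain = 0, elc_gain = 0))
    coh <- generate_cohort(cfg)
    win <- coh[abs(coh$age - 5) <= 0.25, ]
    S <- cov(as.matrix(win[, grep("^roi", names(coh))]))
    Rt <- true_correlation(cfg, 5, list(mated = "high"))
    sdv <- dynscn:::sd_curve_at(cfg, 5)
    norm(S - diag(sdv) %*% Rt %*% diag(sdv), "F")
  }
  errs_small <- vapply(1:20, function(s) err_for(400, s), numeric(1))
  errs_big <- vapply(1:20, function(s) err_for(2000, 100 + s), numeric(1))
  expect_lt(mean(errs_big), mean(errs_small))
})

test_that("cohort and configuration round-trip through text files", {
  cfg <- quick_config(n_children = 25, m_rois = 4, seed = 6)
  coh <- generate_cohort(cfg)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  coh2 <- read_cohort(f)
  expect_equal(coh2$age, coh$age, tolerance = 1e-14)
  expect_identical(coh2$child_id, coh$child_id)
  expect_equal(as.matrix(coh2[, grep("^roi", names(coh2))]),
               as.matrix(coh[, grep("^roi", names(coh))]),
               tolerance = 1e-14, ignore_attr = TRUE)

  g <- tempfile(fileext = ".json")
  write_synthetic_config(cfg, g)
  cfg2 <- read_synthetic_config(g)
  expect_equal(cfg2, cfg)
  # regenerating from the restored config gives the identical cohort
  expect_identical(generate_cohort(cfg2), coh)
  # function-valued dynamics cannot be serialized
  cfgf <- quick_config(rho_within = function(t, g) 0.3,
                       rho_between = function(t, g) 0.1)
  expect_error(write_synthetic_config(cfgf, g), "cannot be serialized")
})

test_that("a child-level random effect preserves marginal structure", {
  cfg <- quick_config(n_children = 40, m_rois = 4, seed = 7,
                      child_effect_sd = 0.1)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh) > 0, TRUE)
  expect_true(all(is.finite(as.matrix(coh[, grep("^roi", names(coh))]))))
})
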