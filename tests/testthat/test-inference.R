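# integrated measures, variance statistic, permutation machinery

test_that("the integrated measure is the defined right-tail Riemann sum", {
  ages <- 1:9
  v <- rep(0.3, 9)
  # j = N: single term with spacing t_N - t_{N-1} = 1
  expect_equal(integrated_measure(v, ages, 9), 0.3)
  # constant curve, j = 1: spacings (1-0) + 8 * 1 = 9
  expect_equal(integrated_measure(v, ages, 1), 2.7)
  expect_equal(integrated_measure(rep(0, 9), ages, 4), 0)
  # non-uniform grid, computed by hand:
  # ages (1, 2.5, 5), dt = (1, 1.5, 2.5); j = 2: 0.2*1.5 + 0.4*2.5
  expect_equal(integrated_measure(c(0.1, 0.2, 0.4), c(1, 2.5, 5), 2),
               0.2 * 1.5 + 0.4 * 2.5)
  expect_error(integrated_measure(v, ages, 10), "out of range")
  # the vectorized form agrees index by index
  set.seed(61)
  vv <- runif(9)
  all_I <- dynscn:::integrated_measures_all(vv, ages)
  for (j in 1:9)
    expect_equal(all_I[j], integrated_measure(vv, ages, j))
})

test_that("the group variance statistic matches hand evaluation", {
  expect_equal(group_variance_statistic(c(2, 2, 2, 2)), 0)
  # (0,0,0,2): mean 0.5; (3*0.25 + 2.25)/3 = 1
  expect_equal(group_variance_statistic(c(0, 0, 0, 2)), 1)
  expect_equal(group_variance_statistic(c(0, 0, 0, 2) + 17),
               group_variance_statistic(c(0, 0, 0, 2)))
  # K = 3 uses divisor 2
  expect_equal(group_variance_statistic(c(0, 0, 3)), 3)
  expect_error(group_variance_statistic(5), "two groups")
})

test_that("p-values use >= (a permutation tying the observed counts)", {
  # handcrafted curves: permutation 1 reproduces the observed curves
  # exactly, permutation 2 is flat -> p must include the tie
  K <- 4; N <- 3
  obs <- matrix(c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2, 3, 4), K, N)
  flat <- matrix(1, K, N)
  cube <- array(c(obs, obs, flat), dim = c(K, N, 3))
  fit <- list(group = factor(c("a", "b", "c", "d")),
              bandwidths = list(), kernel = list(family = "gaussian"))
  res <- dynscn:::assemble_permtest(cube, ages = c(1, 2, 3),
                                    measure = "modularity", Q = 2,
                                    seed = 1, unit = "visit",
                                    length_rule = "weight",
                                    scheme = "groups", fit = fit,
                                    add_one = FALSE, keep_perm = TRUE)
  expect_equal(res$results$p, rep(0.5, 3))  # tie counted, flat not
  # add-one correction shifts the estimator as documented
  res1 <- dynscn:::assemble_permtest(cube, ages = c(1, 2, 3),
                                     measure = "modularity", Q = 2,
                                     seed = 1, unit = "visit",
                                     length_rule = "weight",
                                     scheme = "groups", fit = fit,
                                     add_one = TRUE, keep_perm = FALSE)
  expect_equal(res1$results$p, rep(2 / 3, 3))
})

test_that("identical evaluation scores force a zero statistic and p = 1", {
  cfg <- quick_config(n_children = 80, m_rois = 5, seed = 17)
  coh <- generate_cohort(cfg)
  res <- permutation_test_elc(coh, scores = c(100, 100, 100), Q = 5,
                              ages = c(3, 6), seed = 2)
  expect_equal(res$results$T_obs, c(0, 0))
  expect_equal(res$results$p, c(1, 1))
})

test_that("tests are reproducible and order-invariant given (Q, seed)", {
  cfg <- quick_config(n_children = 100, m_rois = 5, seed = 18)
  coh <- generate_cohort(cfg)
  a <- permutation_test_groups(coh, Q = 30, seed = 7, ages = c(2, 5, 8))
  b <- permutation_test_groups(coh, Q = 30, seed = 7, ages = c(2, 5, 8))
  expect_identical(a$results, b$results)
  c_ <- permutation_test_groups(coh, Q = 30, seed = 8, ages = c(2, 5, 8))
  expect_false(identical(a$results$p, c_$results$p))

  e1 <- permutation_test_elc(coh, Q = 20, seed = 7, ages = c(2, 5, 8))
  e2 <- permutation_test_elc(coh, Q = 20, seed = 7, ages = c(2, 5, 8))
  expect_identical(e1$results, e2$results)
})

test_that("the observed statistic pipeline is byte-identical to the
           manual series + measures route", {
  cfg <- quick_config(n_children = 90, m_rois = 6, seed = 19)
  coh <- generate_cohort(cfg)
  ages <- c(2, 5, 8)
  thetas <- default_thresholds()
  pt <- permutation_test_groups(coh, Q = 2, seed = 3, ages = ages,
                                thresholds = thetas)
  # manual route: per-cell prediction -> thresholding -> exact communities
  fit <- frechet_scn(coh, group = "sex_mated")
  manual <- sapply(levels(fit$group), function(g) {
    sapply(ages, function(a) {
      R <- predict(fit, ages = a, groups = g)
      vals <- vapply(thetas, function(th) {
        # empty networks at high thresholds warn by design; Q is still 0
        suppressWarnings(
          detect_communities(threshold_network(R, th))$modularity)
      }, numeric(1))
      average_over_thresholds(vals, thetas)
    })
  })
  expect_identical(as.numeric(pt$observed_curves),
                   as.numeric(t(manual)))
})

test_that("child-level permutation keeps each child's visits together", {
  cfg <- synthetic_config(n_children = 60, m_rois = 5, seed = 20,
                          visits_pmf = c(0, 0, 1, rep(0, 5)))
  coh <- generate_cohort(cfg)  # 3 visits per child
  pt <- permutation_test_groups(coh, Q = 10, seed = 4, ages = c(3, 6),
                                unit = "child")
  expect_s3_class(pt, "scn_permtest")
  expect_true(all(pt$results$p >= 0 & pt$results$p <= 1))
  pe <- permutation_test_elc(coh, Q = 10, seed = 4, ages = c(3, 6),
                             unit = "child")
  expect_true(all(pe$results$p >= 0 & pe$results$p <= 1))
})

test_that("printing reports the test setup and per-age table", {
  cfg <- quick_config(n_children = 80, m_rois = 5, seed = 21)
  coh <- generate_cohort(cfg)
  pt <- permutation_test_groups(coh, Q = 5, seed = 1, ages = c(4, 7))
  expect_output(print(pt), "Permutation test")
  expect_output(print(pt), "Q = 5")
})
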