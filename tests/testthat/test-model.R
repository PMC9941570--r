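# the frechet_scn model object and its methods

test_that("fitting, printing and summarizing work end to end", {
  cfg <- quick_config(n_children = 80, m_rois = 5, seed = 12)
  coh <- generate_cohort(cfg)
  fit <- frechet_scn(coh)
  expect_s3_class(fit, "frechet_scn")
  expect_output(print(fit), "Frechet regression")
  s <- summary(fit)
  expect_output(print(s), "bandwidth")
  expect_equal(s$n_visits, nrow(coh))
  expect_equal(s$m_rois, 5)

  # residuals + fitted reconstruct the data
  expect_equal(residuals(fit) + fitted(fit),
               as.matrix(coh[, grep("^roi", names(coh))]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("predictions are valid correlation/adjacency matrices", {
  cfg <- quick_config(n_children = 120, m_rois = 6, seed = 13)
  coh <- generate_cohort(cfg)
  fit <- frechet_scn(coh, group = "sex_mated")
  R <- predict(fit, ages = 5, groups = "M_high")
  expect_equal(diag(unclass(R)), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(R >= -1 & R <= 1))
  expect_equal(unclass(R), t(unclass(R)))
  A <- predict(fit, ages = 5, groups = "M_high", what = "adjacency",
               theta = 0.7)
  expect_true(all(unclass(A) == 0 | unclass(A) >= 0.7))
  expect_equal(diag(unclass(A)), rep(0, 6), ignore_attr = TRUE)
  # multiple cells come back as a nested list
  out <- predict(fit, ages = c(3, 5), groups = c("F_low", "M_high"))
  expect_named(out, c("F_low", "M_high"))
  expect_named(out$F_low, c("3", "5"))
})

test_that("the bivariate fit collapses to the 1-D fit when the score
           carries no information", {
  # mirrored design: every visit appears twice with scores z +- delta, so
  # all score moments vanish at the score mean and the bivariate weights
  # reduce exactly to the age-only weights
  cfg <- quick_config(n_children = 100, m_rois = 5, seed = 14)
  coh <- generate_cohort(cfg)
  dup <- rbind(coh, coh)
  dup$elc <- rep(c(95, 105), each = nrow(coh))
  fit1 <- frechet_scn(coh, bandwidth = 0.8, mean_bandwidth = 0.8)
  fit2 <- frechet_scn(dup, elc = "elc", elc_bandwidth = 20,
                      bandwidth = 0.8, mean_bandwidth = 0.8)
  for (t in c(3, 7)) {
    R1 <- predict(fit1, ages = t)
    R2 <- predict(fit2, ages = t, scores = 100)
    expect_lt(norm(unclass(R1) - unclass(R2), "F"), 1e-3)
  }
})

test_that("plot produces measure curves without error", {
  cfg <- quick_config(n_children = 100, m_rois = 5, seed = 15)
  coh <- generate_cohort(cfg)
  fit <- frechet_scn(coh, group = "sex_mated")
  pdf(NULL)
  on.exit(dev.off())
  curves <- plot(fit, ages = c(3, 6), thresholds = c(0.6, 0.8))
  expect_s3_class(curves, "data.frame")
  expect_equal(nrow(curves), 4 * 2)
})

test_that("misuse is caught early", {
  cfg <- quick_config(n_children = 30, m_rois = 4, seed = 16)
  coh <- generate_cohort(cfg)
  expect_error(frechet_scn(coh, elc = "elc", group = "sex_mated"),
               "mutually exclusive")
  expect_error(frechet_scn(coh, group = "nope"), "no column")
  expect_error(frechet_scn(coh[, 1:5]), "ROI")
  fit <- frechet_scn(coh)
  expect_error(predict(fit, ages = 5, scores = 100), "bivariate")
  fitg <- frechet_scn(coh, group = "sex_mated")
  expect_error(predict(fitg, ages = 5, groups = "X"), "unknown group")
})
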