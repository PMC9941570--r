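# raw covariances, PSD projection, and the closed-form Frechet mean

test_that("raw covariances are residual outer products", {
  ages <- c(1, 3, 5, 7)
  Y <- cbind(2 + 0.5 * ages, 1 + ages)  # exactly linear -> zero residuals
  df <- data.frame(age = ages, roi_001 = Y[, 1], roi_002 = Y[, 2])
  mu <- estimate_mean_function(df, bandwidth = 1)
  raws <- compute_raw_covariances(df, mu)
  expect_length(raws, 4)
  for (r in raws)
    expect_equal(r$matrix, matrix(0, 2, 2), tolerance = 1e-8,
                 ignore_attr = TRUE)

  # hand case: residual (1, 2) -> [[1,2],[2,4]]; trace = |r|^2
  df2 <- df
  df2$roi_001[2] <- df2$roi_001[2] + 1
  df2$roi_002[2] <- df2$roi_002[2] + 2
  mu2 <- estimate_mean_function(df, bandwidth = 1)  # mean fit from clean data
  raws2 <- compute_raw_covariances(df2, mu2)
  expect_equal(raws2[[2]]$matrix, matrix(c(1, 2, 2, 4), 2),
               tolerance = 1e-6, ignore_attr = TRUE)
  resid <- attr(raws2, "resid")
  for (i in seq_along(raws2))
    expect_equal(sum(diag(raws2[[i]]$matrix)), sum(resid[i, ]^2))
})

test_that("nearest_psd clips negative eigenvalues and is idempotent", {
  # [[1,2],[2,1]] has eigenvalues 3 and -1; projection by hand gives
  # 3/2 * vv' with v = (1,1)/sqrt(2)
  A <- matrix(c(1, 2, 2, 1), 2)
  P <- nearest_psd(A)
  expect_equal(P, matrix(1.5, 2, 2), tolerance = 1e-12)
  expect_equal(nearest_psd(P), P, tolerance = 1e-12)
  expect_equal(nearest_psd(diag(3)), diag(3))
  expect_error(nearest_psd(matrix(c(1, NA, NA, 1), 2)), "finite")
  expect_error(nearest_psd(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("the weighted Frechet mean handles negative weights by clipping", {
  # weighted average diag(1.5, -0.5) -> clip -> diag(1.5, 0)
  est <- weighted_frechet_mean(list(diag(c(1, 0)), diag(c(0, 1))),
                               c(1.5, -0.5))
  expect_equal(est, diag(c(1.5, 0)), tolerance = 1e-12)
  # identical inputs reproduce themselves for any valid weights
  C <- matrix(c(2, 1, 1, 3), 2)
  expect_equal(weighted_frechet_mean(list(C, C, C), c(0.2, 0.5, 0.3)), C,
               tolerance = 1e-12)
  expect_error(weighted_frechet_mean(list(C, C), c(1, -1)),
               "numerically zero")
})

test_that("closed form equals an iterative minimizer of the objective", {
  set.seed(31)
  for (r in 1:5) {
    m <- sample(3:5, 1)
    mats <- lapply(1:8, function(i) {
      v <- rnorm(m)
      tcrossprod(v)  # rank-1, like raw covariances
    })
    w <- rnorm(8, 1, 0.8)        # includes negative weights
    if (sum(w) < 0.5) w <- w + 1
    closed <- weighted_frechet_mean(mats, w)
    iter <- oracle_projected_gradient(mats, w)
    expect_lt(norm(closed - iter, "F"), 1e-6)
  }
})

test_that("frechet_covariance_at agrees with the fit-object fast path", {
  set.seed(32)
  cfg <- quick_config(n_children = 60, m_rois = 5, seed = 9)
  coh <- generate_cohort(cfg)
  fit <- frechet_scn(coh)
  mu <- estimate_mean_function(coh, bandwidth = fit$bandwidths$mean)
  raws <- compute_raw_covariances(coh, mu)
  for (t in c(3, 6)) {
    op <- frechet_covariance_at(t, raws, "gaussian",
                                fit$bandwidths$age)
    fast <- predict(fit, ages = t, what = "covariance")
    expect_equal(unclass(op), unclass(fast), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # effective-sample-size diagnostic is recorded
  expect_true(attr(frechet_covariance_at(5, raws), "ess") > 0)
})
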