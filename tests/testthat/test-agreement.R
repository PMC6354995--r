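test_that("correlation stats behave like Pearson r and its square", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0)
  expect_equal(correlation_stats(x, x), list(r = 1, r_squared = 1))
  expect_equal(correlation_stats(x, -x)$r, -1)
  y <- c(1.0, 2.8, 2.9, 4.4, 5.6)
  # direct formula evaluation as oracle
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  cs <- correlation_stats(x, y)
  expect_equal(cs$r, r_hand)
  expect_equal(cs$r_squared, r_hand^2)
  expect_error(correlation_stats(x, rep(1, 5)), "zero variance")
  expect_error(correlation_stats(1:2, 2:3), "at least 3")
})

test_that("correlation is invariant under affine transforms up to sign", {
  withr::with_seed(5, {
    x <- rnorm(20); y <- x + rnorm(20, 0, 0.5)
    base <- correlation_stats(x, y)$r
    expect_equal(correlation_stats(2 * x + 3, y)$r, base)
    expect_equal(correlation_stats(x, -4 * y + 1)$r, -base)
  })
})

test_that("SEE follows the residual formula with n - p denominator", {
  crit <- c(1, 2, 3, 4); pred <- crit + c(1, -1, 1, -1)
  expect_equal(standard_error_estimate(crit, pred, n_params = 2), sqrt(2))
  expect_equal(standard_error_estimate(crit, crit), 0)
  expect_error(standard_error_estimate(crit[1:3], crit[1:3], n_params = 3),
               "undefined")
  # SEE = RMSE * sqrt(n / (n - p)) on the same residuals
  withr::with_seed(8, {
    crit <- rnorm(40, 3); pred <- crit + rnorm(40, 0, 0.4)
    rmse <- sqrt(mean((pred - crit)^2))
    expect_equal(standard_error_estimate(crit, pred, 3),
                 rmse * sqrt(40 / 37))
  })
})

test_that("Bland-Altman bias and limits match hand arithmetic", {
  x <- c(2, 3, 4)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_half_width, 0)
  ba <- bland_altman(c(0, 0), c(-1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_half_width, 1.96 * sqrt(2))
  bc <- bland_altman(x, x + 0.7)
  expect_equal(bc$bias, 0.7)
  expect_equal(bc$loa_half_width, 0)
  expect_equal(unname(bc$loa), c(0.7, 0.7))
  # direction: predicted minus criterion
  expect_lt(bland_altman(c(5, 5), c(3, 4))$bias, 0)
})

test_that("error statistics match element-wise definitions", {
  et <- error_stats(data.frame(task = "walk", criterion = 2, predicted = 3))
  expect_equal(et$mae, c(1, 1))
  expect_equal(et$mape, c(50, 50))
  expect_equal(et$signed_error, c(1, 1))
  expect_equal(et$rmse, c(1, 1))

  perfect <- error_stats(data.frame(task = rep(c("a", "b"), 3),
                                    criterion = 1:6, predicted = 1:6))
  expect_true(all(perfect$mae == 0 & perfect$rmse == 0))

  expect_warning(
    zr <- error_stats(data.frame(task = "rest", criterion = c(0, 0),
                                 predicted = c(0.2, -0.1))),
    "MAPE undefined")
  expect_true(all(is.na(zr$mape)))
})

test_that("MAE never exceeds RMSE; equal only for constant magnitudes", {
  withr::with_seed(9, {
    for (i in 1:20) {
      d <- data.frame(task = "t", criterion = runif(15, 1, 5))
      d$predicted <- d$criterion + rnorm(15)
      et <- error_stats(d)
      expect_lte(et$mae[1], et$rmse[1] + 1e-12)
    }
  })
  same <- data.frame(task = "t", criterion = c(1, 2, 3),
                     predicted = c(2, 1, 4))  # |d| = 1 throughout
  et <- error_stats(same)
  expect_equal(et$mae[1], et$rmse[1])
})

test_that("sample-size computation reproduces the design numbers", {
  expect_equal(power_sample_size(d = 1.0, alpha = 0.05, power = 0.8), 8L)
  expect_equal(power_sample_size(d = 0.5, alpha = 0.05, power = 0.8), 32L)
  expect_equal(power_sample_size(d = 100), 1L)
  expect_error(power_sample_size(d = 0), "'d'")
  expect_error(power_sample_size(d = 1, alpha = 1.2), "alpha")
})

test_that("agreement_report assembles all statistics coherently", {
  withr::with_seed(11, {
    crit <- runif(30, 1, 6); pred <- crit + rnorm(30, 0.2, 0.5)
    rep <- agreement_report(crit, pred)
    expect_equal(rep$r, cor(crit, pred))
    expect_equal(rep$bias, mean(pred - crit))
    expect_equal(rep$see, standard_error_estimate(crit, pred, 3))
    expect_equal(rep$n, 30)
  })
})
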