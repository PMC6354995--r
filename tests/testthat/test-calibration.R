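test_that("OLS fit matches the normal-equations oracle on random instances", {
  withr::with_seed(10, {
    for (i in 1:25) {
      rec <- toy_records(n_participants = 5, tasks_per = 2, noise_sd = 0.6,
                         seed = sample.int(1e6, 1))
      fit <- fit_paee_model(rec)
      oracle <- ols_oracle(as.matrix(rec[, c("pac", "hr")]),
                           rec$criterion_paee)
      expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-9)
    }
  })
})

test_that("noiseless records recover the published coefficients exactly", {
  rec <- toy_records(n_participants = 4, tasks_per = 3, noise_sd = 0)
  fit <- fit_paee_model(rec)
  k <- coef(fit)
  expect_equal(k[["intercept"]], -2.713284, tolerance = 1e-9)
  expect_equal(k[["pac"]], 0.000453, tolerance = 1e-9)
  expect_equal(k[["hr"]], 0.045487, tolerance = 1e-9)
  expect_equal(fit$see, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("four-point fit equals the hand normal-equations solution", {
  rec <- data.frame(participant = c("a", "b", "c", "d"),
                    pac = c(0, 1000, 2000, 4000),
                    hr = c(60, 80, 95, 120),
                    criterion_paee = c(0.1, 1.4, 2.4, 4.9))
  fit <- fit_paee_model(rec)
  oracle <- ols_oracle(as.matrix(rec[, c("pac", "hr")]), rec$criterion_paee)
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-9)
  # residuals of an OLS fit with intercept sum to zero
  pred <- predict(fit, rec)
  expect_equal(sum(rec$criterion_paee - pred), 0, tolerance = 1e-9)
})

test_that("rank deficiency is a singular-fit error naming the column", {
  rec <- toy_records(4, 2)
  rec$hr <- 100
  expect_error(fit_paee_model(rec), "singular fit.*hr")
  expect_error(fit_paee_model(rec[1:3, ]), "at least")
})

test_that("prediction applies the linear equation, optionally clamped", {
  ms <- printed_models()
  expect_equal(predict_paee(ms$unilateral, 0, 1e-9), -2.713284,
               tolerance = 1e-6)
  expect_equal(predict_paee(ms$unilateral, 3353, 106), 3.627247,
               tolerance = 1e-6)
  expect_equal(predict_paee(ms$bilateral, 5235, 142), 5.243209,
               tolerance = 1e-6)
  # consistent with the reference criterion at those group means
  expect_equal(predict_paee(ms$unilateral, 3353, 106), 3.61, tolerance = 0.02)
  expect_equal(predict_paee(ms$bilateral, 5235, 142), 5.23, tolerance = 0.01)
  expect_equal(predict_paee(ms$unilateral, 0, 10, clamp_zero = TRUE), 0)
  expect_error(predict_paee(ms$unilateral, -5, 100), "pac")
})

test_that("LOOCV leaves out whole participants and matches per-fold oracle", {
  rec <- toy_records(n_participants = 3, tasks_per = 4, noise_sd = 0.5,
                     seed = 42)
  cv <- loocv_predict(rec)
  expect_equal(length(unique(cv$fold)), 3)
  expect_false(any(is.na(cv$predicted)))
  for (pid in unique(rec$participant)) {
    hold <- rec$participant == pid
    beta <- ols_oracle(as.matrix(rec[!hold, c("pac", "hr")]),
                       rec$criterion_paee[!hold])
    want <- beta[1] + beta[2] * rec$pac[hold] + beta[3] * rec$hr[hold]
    expect_equal(cv$predicted[hold], unname(want), tolerance = 1e-9)
  }
})

test_that("LOOCV is exact when participants are exchangeable and noiseless", {
  rec <- toy_records(n_participants = 5, tasks_per = 3, noise_sd = 0)
  cv <- loocv_predict(rec)
  expect_equal(cv$predicted, rec$criterion_paee, tolerance = 1e-9)
})

test_that("LOOCV error is no smaller than in-sample error", {
  errs <- withr::with_seed(7, vapply(1:30, function(i) {
    rec <- toy_records(n_participants = 6, tasks_per = 4, noise_sd = 0.8,
                       seed = sample.int(1e6, 1))
    fit <- fit_paee_model(rec)
    ins <- mean((rec$criterion_paee - predict(fit, rec))^2)
    cv <- loocv_predict(rec)
    c(ins = ins, out = mean((cv$criterion_paee - cv$predicted)^2))
  }, numeric(2)))
  expect_gt(mean(errs["out", ] - errs["ins", ]), 0)
  # and on every one of these instances
  expect_true(all(errs["out", ] >= errs["ins", ]))
})

test_that("the participant bootstrap resamples and refits", {
  rec <- toy_records(n_participants = 5, tasks_per = 4, noise_sd = 0.5)
  b <- bootstrap_models(rec, B = 25, seed = 3)
  expect_equal(ncol(b), 3)
  expect_equal(nrow(b), 25)
  expect_identical(b, bootstrap_models(rec, B = 25, seed = 3))
  # centred near the full-sample fit
  expect_equal(unname(colMeans(b)), unname(coef(fit_paee_model(rec))),
               tolerance = 0.5)
})

test_that("HR-only comparator uses the same machinery minus the PAC column", {
  rec <- toy_records(n_participants = 4, tasks_per = 4, noise_sd = 0.3)
  fit <- fit_paee_model(rec, predictors = "hr")
  expect_named(coef(fit), c("intercept", "hr"))
  expect_equal(unname(coef(fit)),
               unname(ols_oracle(as.matrix(rec[, "hr", drop = FALSE]),
                                 rec$criterion_paee)),
               tolerance = 1e-9)
})
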