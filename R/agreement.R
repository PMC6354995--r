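# Agreement between criterion and predicted PAEE: correlation, standard
# error of the estimate, Bland-Altman limits of agreement, per-activity
# error statistics, and the study-design power computation.

#' Pearson correlation between criterion and predicted series
#'
#' @param criterion,predicted Numeric vectors of equal length (n >= 3,
#'   non-zero variance in both).
#' @return List with `r` and `r_squared`.
#' @export
#' @examples
#' correlation_stats(1:5, c(1.1, 2.0, 2.9, 4.2, 5.1))
correlation_stats <- function(criterion, predicted) {
  stop_if(length(criterion) != length(predicted),
          "'criterion' and 'predicted' must have equal length")
  stop_if(length(criterion) < 3, "need at least 3 pairs")
  stop_if(sd(criterion) == 0 || sd(predicted) == 0,
          "correlation undefined: a series has zero variance")
  r <- cor(criterion, predicted)
  list(r = r, r_squared = r^2)
}

#' Standard error of the estimate
#'
#' Residual standard deviation of a prediction,
#' `sqrt(sum((criterion - predicted)^2) / (n - n_params))`.  The default
#' `n_params = 3` matches the two-predictor model with intercept.
#'
#' @param criterion,predicted Numeric vectors.
#' @param n_params Number of model parameters consumed (denominator
#'   `n - n_params` must be positive).
#' @return SEE, same units as the series (kcal·min⁻¹ here).
#' @export
standard_error_estimate <- function(criterion, predicted, n_params = 3) {
  n <- length(criterion)
  stop_if(n <= n_params, "SEE undefined: need n > n_params (", n, " <= ",
          n_params, ")")
  sqrt(sum((criterion - predicted)^2) / (n - n_params))
}

#' Bland-Altman agreement
#'
#' Differences are `predicted - criterion`; bias is their mean and the 95 %
#' limits of agreement are `bias ± multiplier * SD` (sample SD, n − 1;
#' multiplier 1.96 by default).
#'
#' @param criterion,predicted Numeric vectors (n >= 2).
#' @param multiplier LoA multiplier (1.96 for 95 % limits).
#' @return Object of class `bland_altman`: `bias`, `loa_half_width`,
#'   `loa` (lower, upper), `differences`, `means`, `n`.
#' @export
#' @examples
#' ba <- bland_altman(c(2, 3, 4), c(2.2, 2.9, 4.3))
#' ba$bias
bland_altman <- function(criterion, predicted, multiplier = 1.96) {
  stop_if(length(criterion) != length(predicted),
          "'criterion' and 'predicted' must have equal length")
  stop_if(length(criterion) < 2, "need at least 2 pairs")
  d <- predicted - criterion
  bias <- mean(d)
  half <- multiplier * sd(d)
  structure(list(bias = bias, loa_half_width = half,
                 loa = c(lower = bias - half, upper = bias + half),
                 differences = d, means = (criterion + predicted) / 2,
                 n = length(d), multiplier = multiplier),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f +/- %.3f (LoA %.3f to %.3f)\n",
              x$n, x$bias, x$loa_half_width, x$loa[["lower"]],
              x$loa[["upper"]]))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against pair means with the bias and limits of agreement.
#'
#' @param x A [bland_altman()] object.
#' @param ... Passed to [plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of criterion and predicted (kcal/min)",
                 ylab = "Predicted - criterion (kcal/min)", ...)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = x$loa, lty = 2)
  invisible(x)
}

#' Per-activity error statistics
#'
#' MAE, MAPE, mean signed error and RMSE of `predicted - criterion`, per
#' task and overall.  MAPE is computed only over pairs with positive
#' criterion (at rest criterion PAEE is 0 and a percentage error is
#' undefined); if a stratum has no such pairs its MAPE is `NA` with a
#' warning.
#'
#' @param pairs Data frame with columns `task`, `criterion`, `predicted`.
#' @param exclude_zero_criterion Drop `criterion <= 0` pairs from MAPE
#'   (default TRUE).
#' @return Data frame of class `error_table`: `task`, `n`, `mae`, `mape`,
#'   `signed_error`, `rmse`; last row is `"overall"`.
#' @export
#' @examples
#' error_stats(data.frame(task = "walk", criterion = 2, predicted = 3))
error_stats <- function(pairs, exclude_zero_criterion = TRUE) {
  stop_if(!all(c("task", "criterion", "predicted") %in% names(pairs)),
          "'pairs' must have columns task, criterion, predicted")
  stop_if(nrow(pairs) == 0, "'pairs' is empty")
  one <- function(d, label) {
    err <- d$predicted - d$criterion
    ok <- if (exclude_zero_criterion) d$criterion > 0 else rep(TRUE, nrow(d))
    mape <- if (any(ok))
      mean(abs(err[ok]) / d$criterion[ok]) * 100
    else {
      warning("MAPE undefined for '", label,
              "': no pairs with positive criterion", call. = FALSE)
      NA_real_
    }
    data.frame(task = label, n = nrow(d), mae = mean(abs(err)), mape = mape,
               signed_error = mean(err), rmse = sqrt(mean(err^2)),
               stringsAsFactors = FALSE)
  }
  by_task <- lapply(split(pairs, pairs$task), function(d) one(d, d$task[1]))
  out <- rbind(do.call(rbind, by_task), one(pairs, "overall"))
  rownames(out) <- NULL
  class(out) <- c("error_table", "data.frame")
  out
}

#' Sample size for a paired comparison
#'
#' Normal-approximation paired/one-sample form:
#' `n = ceil(((z_{1-alpha/2} + z_{power}) / d)^2)` for effect size Cohen's
#' d.  With d = 1.0, alpha = 0.05, power = 0.8 this gives n = 8.
#'
#' @param d Cohen's d (> 0).
#' @param alpha Two-sided type-I error rate, in (0, 1).
#' @param power Target power, in (0, 1).
#' @return Required sample size (integer >= 1).
#' @export
#' @examples
#' power_sample_size(d = 1.0)   # 8
power_sample_size <- function(d, alpha = 0.05, power = 0.8) {
  stop_if(d <= 0, "'d' must be > 0")
  stop_if(alpha <= 0 || alpha >= 1, "'alpha' must be in (0, 1)")
  stop_if(power <= 0 || power >= 1, "'power' must be in (0, 1)")
  max(1L, as.integer(ceiling(((qnorm(1 - alpha / 2) + qnorm(power)) / d)^2)))
}

#' Full agreement report for one criterion-prediction pairing
#'
#' @param criterion,predicted Numeric vectors.
#' @param n_params Parameters consumed by the model behind `predicted`
#'   (for the SEE denominator).
#' @return List with `r`, `r_squared`, `see`, `bias`, `loa_half_width`,
#'   `n`.
#' @export
agreement_report <- function(criterion, predicted, n_params = 3) {
  cs <- correlation_stats(criterion, predicted)
  ba <- bland_altman(criterion, predicted)
  list(r = cs$r, r_squared = cs$r_squared,
       see = standard_error_estimate(criterion, predicted, n_params),
       bias = ba$bias, loa_half_width = ba$loa_half_width,
       n = length(criterion))
}
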