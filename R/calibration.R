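# Calibration: ordinary least-squares PAEE prediction models on
# steady-state records, with leave-one-participant-out cross-validation and
# an optional participant bootstrap.

new_paee_model <- function(coefficients, predictors, group = NA_character_,
                           r = NA_real_, r_squared = NA_real_,
                           see = NA_real_, n = NA_integer_,
                           source = "fitted") {
  structure(list(coefficients = coefficients, predictors = predictors,
                 group = group, r = r, r_squared = r_squared, see = see,
                 n = n, source = source),
            class = "paee_model")
}

#' Fit a PAEE prediction model
#'
#' Ordinary least squares of criterion PAEE on accelerometer counts and
#' heart rate (`criterion_paee ~ pac + hr`), or on any subset of those
#' predictors (`predictors = "hr"` gives the HR-only comparator).
#' Diagnostics: Pearson r between fitted and criterion, R², and the
#' standard error of the estimate with denominator `n - p` (p = number of
#' coefficients including the intercept).
#'
#' @param records Data frame with columns `criterion_paee` and the
#'   requested predictors (plus `participant` for cross-validation).
#' @param predictors Character vector of predictor columns.
#' @return An object of class `paee_model`.
#' @export
#' @examples
#' rec <- data.frame(pac = c(0, 1000, 2000, 3000), hr = c(60, 80, 85, 100))
#' rec$criterion_paee <- -2.7 + 0.0005 * rec$pac + 0.04 * rec$hr
#' coef(fit_paee_model(rec))
fit_paee_model <- function(records, predictors = c("pac", "hr")) {
  stop_if(!all(c("criterion_paee", predictors) %in% names(records)),
          "records must have columns: criterion_paee, ",
          paste(predictors, collapse = ", "))
  n <- nrow(records)
  p <- length(predictors) + 1
  stop_if(n < p + 1, "need at least ", p + 1, " records to fit ", p,
          " coefficients")
  X <- cbind(intercept = 1,
             as.matrix(records[, predictors, drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("singular fit: design matrix rank-deficient (offending column",
         if (length(dropped) > 1) "s" else "", ": ",
         paste(dropped, collapse = ", "), ")", call. = FALSE)
  }
  fml <- stats::reformulate(predictors, response = "criterion_paee")
  fit <- lm(fml, data = records)
  y <- records$criterion_paee
  fitted <- unname(fitted(fit))
  res <- y - fitted
  r <- if (sd(fitted) > 0 && sd(y) > 0) cor(y, fitted) else NA_real_
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  cf <- coef(fit)
  names(cf)[1] <- "intercept"
  grp <- if ("group" %in% names(records)) unique(records$group) else NA_character_
  new_paee_model(cf, predictors = predictors,
                 group = if (length(grp) == 1) grp else NA_character_,
                 r = r, r_squared = r2,
                 see = sqrt(sum(res^2) / (n - p)), n = n)
}

#' Predict PAEE from a model
#'
#' `PAEE = intercept + beta_pac * PAC + beta_hr * HR` (terms for the
#' model's own predictors only).  No truncation by default; `clamp_zero`
#' floors predictions at zero.
#'
#' @param model A [paee_model][fit_paee_model()] (fitted or printed
#'   fixture).
#' @param pac Accelerometer counts·min⁻¹ (>= 0).
#' @param hr Heart rate, bpm (> 0).
#' @param clamp_zero Floor predictions at 0.
#' @return Predicted PAEE, kcal·min⁻¹.
#' @export
#' @examples
#' predict_paee(printed_models()$unilateral, 3353, 106)   # ~3.63
predict_paee <- function(model, pac = NULL, hr = NULL, clamp_zero = FALSE) {
  stop_if(!inherits(model, "paee_model"), "'model' must be a paee_model")
  vars <- list(pac = pac, hr = hr)
  out <- model$coefficients[["intercept"]]
  for (v in model$predictors) {
    stop_if(is.null(vars[[v]]), "predictor '", v, "' required by this model")
    if (v == "pac") stop_if(any(vars[[v]] < 0), "'pac' must be >= 0")
    if (v == "hr") stop_if(any(vars[[v]] <= 0), "'hr' must be > 0")
    out <- out + model$coefficients[[v]] * vars[[v]]
  }
  if (clamp_zero) out <- pmax(out, 0)
  out
}

#' @export
predict.paee_model <- function(object, newdata, clamp_zero = FALSE, ...) {
  predict_paee(object, pac = newdata$pac, hr = newdata$hr,
               clamp_zero = clamp_zero)
}

#' @export
coef.paee_model <- function(object, ...) object$coefficients

#' @export
print.paee_model <- function(x, ...) {
  terms <- vapply(x$predictors, function(v)
    sprintf("%.6f*%s", x$coefficients[[v]], toupper(v)), character(1))
  cat(sprintf("PAEE model (%s, %s): PAEE = %s %+0.6f\n",
              x$group %||% "?", x$source, paste(terms, collapse = " + "),
              x$coefficients[["intercept"]]))
  if (!is.na(x$r))
    cat(sprintf("  r = %.3f, R^2 = %.3f, SEE = %.3f kcal/min, n = %s\n",
                x$r, x$r_squared, x$see,
                ifelse(is.na(x$n), "NA", x$n)))
  invisible(x)
}

#' Leave-one-participant-out cross-validated predictions
#'
#' For each participant: refit the model on every other participant's
#' records and predict the held-out records.  The resampling unit is the
#' participant, not the observation, so no within-subject information
#' leaks into a fold.  A fold whose training set is singular is skipped
#' with a warning (predictions `NA`).
#'
#' @param records Data frame with columns `participant`, `criterion_paee`
#'   and the predictors.
#' @param predictors Passed to [fit_paee_model()].
#' @return `records` with columns `predicted` and `fold` appended; one
#'   fold per participant.
#' @export
loocv_predict <- function(records, predictors = c("pac", "hr")) {
  stop_if(!"participant" %in% names(records),
          "records must have a 'participant' column")
  ids <- unique(records$participant)
  stop_if(length(ids) < 3, "need >= 3 distinct participants for LOOCV")
  out <- records
  out$predicted <- NA_real_
  out$fold <- match(records$participant, ids)
  for (i in seq_along(ids)) {
    hold <- records$participant == ids[i]
    fit <- tryCatch(fit_paee_model(records[!hold, , drop = FALSE], predictors),
                    error = function(e) {
                      warning("fold ", ids[i], " skipped: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(fit)) next
    out$predicted[hold] <- predict(fit, records[hold, , drop = FALSE])
  }
  out
}

#' Participant bootstrap of model coefficients
#'
#' Optional resampling layer: draw participants with replacement, refit,
#' and collect coefficients — distinct from (and in addition to) the
#' leave-one-participant-out analysis.
#'
#' @param records As for [loocv_predict()].
#' @param B Number of bootstrap replicates.
#' @param seed Seed for the resampling.
#' @param predictors Passed to [fit_paee_model()].
#' @return Matrix of coefficients, one row per successful replicate.
#' @export
bootstrap_models <- function(records, B = 200, seed = 1,
                             predictors = c("pac", "hr")) {
  ids <- unique(records$participant)
  by_id <- split(records, records$participant)
  withr::with_seed(hash_seed(seed, "bootstrap"), {
    rows <- lapply(seq_len(B), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      rec <- do.call(rbind, by_id[take])
      fit <- tryCatch(fit_paee_model(rec, predictors),
                      error = function(e) NULL)
      if (is.null(fit)) NULL else coef(fit)
    })
  })
  do.call(rbind, rows)
}

#' Calibration records from activity summaries
#'
#' One record per completed participant-task: steady-state mean PAC, mean
#' HR and criterion PAEE.  Walking tasks only by default — the calibration
#' models target ambulation and are not constrained through the rest point.
#'
#' @param summaries An [summarize_activities()] data frame.
#' @param include_rest Keep the rest stage records.
#' @return Data frame with columns `participant`, `group`, `task`, `pac`,
#'   `hr`, `criterion_paee`.
#' @export
build_records <- function(summaries, include_rest = FALSE) {
  d <- if (include_rest) summaries else summaries[summaries$velocity > 0, ]
  out <- data.frame(participant = d$id, group = d$group, task = d$task,
                    pac = d$mean_pac, hr = d$mean_hr,
                    criterion_paee = d$paee, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
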