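# Indirect calorimetry: criterion energy expenditure and derived
# physiological quantities from gas-exchange streams.

#' Weir energy expenditure
#'
#' Abbreviated Weir equation (protein oxidation neglected):
#' `EE (kcal·min⁻¹) = 3.941 ·V̇O₂ + 1.106 ·V̇CO₂`, gas volumes in L·min⁻¹.
#' Vectorised and linear.
#'
#' @param vo2,vco2 Oxygen uptake and carbon-dioxide production, L·min⁻¹
#'   (>= 0).
#' @param coefficients Named pair `c(o2 = , co2 = )`; alternative Weir
#'   variants can be supplied here.
#' @return Energy expenditure, kcal·min⁻¹.
#' @export
#' @examples
#' weir_ee(1.0, 0.8)   # 4.8258
weir_ee <- function(vo2, vco2, coefficients = weir_coefficients()) {
  stop_if(any(vo2 < 0) || any(vco2 < 0),
          "'vo2' and 'vco2' must be non-negative")
  coefficients[["o2"]] * vo2 + coefficients[["co2"]] * vco2
}

#' @rdname weir_ee
#' @export
weir_coefficients <- function() c(o2 = 3.941, co2 = 1.106)

#' Resting metabolic rate per minute
#'
#' @param rmr Resting metabolic rate, kcal·day⁻¹ (> 0).
#' @return kcal·min⁻¹ (`rmr / 1440`).
#' @export
#' @examples
#' rmr_per_min(1776)   # 1.2333...
rmr_per_min <- function(rmr) {
  stop_if(any(rmr <= 0), "'rmr' must be positive (kcal per day)")
  rmr / 1440
}

#' Steady-state mean over the final window of a task
#'
#' Arithmetic mean of every numeric field over samples whose epoch start
#' time falls in the final `window` minutes of the task, i.e.
#' `t_s >= (duration - window) * 60`.  A stream that does not extend into
#' the final window (an incomplete task) is an error, not a silent short
#' mean.
#'
#' @param stream Data frame with an epoch start-time column `t_s`
#'   (seconds) and numeric measurement columns.
#' @param duration Task duration, minutes.
#' @param window Averaging window, minutes (default 2).
#' @return Named list of column means plus `n` (samples averaged).
#' @export
#' @examples
#' s <- data.frame(t_s = seq(0, 270, 30), x = 1:10)
#' steady_state_mean(s, duration = 5)$x   # mean of last 4 epochs = 8.5
steady_state_mean <- function(stream, duration, window = STEADY_WINDOW_MIN) {
  stop_if(!"t_s" %in% names(stream), "'stream' must have a 't_s' column")
  start <- (duration - window) * 60
  stop_if(nrow(stream) == 0 || max(stream$t_s) < duration * 60 - EPOCH_S,
          "incomplete task: stream ends before the final ", window,
          "-min window")
  sel <- stream$t_s >= start
  stop_if(!any(sel), "incomplete task: no samples in the final window")
  cols <- setdiff(names(stream)[vapply(stream, is.numeric, logical(1))],
                  "t_s")
  out <- lapply(cols, function(cl) mean(stream[[cl]][sel]))
  names(out) <- cols
  out$n <- sum(sel)
  out
}

#' Criterion physical activity energy expenditure
#'
#' `PAEE = TEE - RMR/1440`.  Negative values are possible (task energy
#' below rest); they are flagged with a warning, never clipped, because
#' clipping would bias downstream agreement statistics.
#'
#' @param tee Total energy expenditure, kcal·min⁻¹ (>= 0).
#' @param resting List or row with field `rmr` (kcal·day⁻¹).
#' @return PAEE, kcal·min⁻¹.
#' @export
#' @examples
#' compute_paee(3.633, list(rmr = 1776))
compute_paee <- function(tee, resting) {
  stop_if(any(tee < 0), "'tee' must be non-negative")
  out <- tee - rmr_per_min(resting$rmr)
  if (any(out < -1e-12))
    warning("negative PAEE (task energy below resting); value kept unclipped",
            call. = FALSE)
  out
}

#' Respiratory exchange ratio
#'
#' @param vo2,vco2 L·min⁻¹; `vo2` must be positive.
#' @return `vco2 / vo2`.
#' @export
compute_rer <- function(vo2, vco2) {
  stop_if(any(vo2 <= 0), "RER undefined: 'vo2' must be > 0")
  rer <- vco2 / vo2
  if (any(rer < 0.6 | rer > 1.3))
    warning("RER outside the physiological range (0.6, 1.3)", call. = FALSE)
  rer
}

#' RMR-referenced METs
#'
#' Task energy expenditure as a multiple of the participant's own resting
#' expenditure: `METs = TEE / (RMR/1440)`, so rest is exactly 1.0.  The
#' fixed-convention alternative (V̇O₂ relative to 3.5 mL·kg⁻¹·min⁻¹) is
#' available via `convention = "vo2_3.5"`, which additionally needs `vo2`
#' and `body_mass`.
#'
#' @param tee Total energy expenditure, kcal·min⁻¹.
#' @param resting List or row with field `rmr` (kcal·day⁻¹).
#' @param convention `"rmr"` (default) or `"vo2_3.5"`.
#' @param vo2 V̇O₂ (L·min⁻¹), required for `"vo2_3.5"`.
#' @param body_mass kg, required for `"vo2_3.5"`.
#' @return METs, dimensionless.
#' @export
#' @examples
#' compute_mets(3.72 + 1596 / 1440, list(rmr = 1596))   # ~4.36
compute_mets <- function(tee, resting, convention = c("rmr", "vo2_3.5"),
                         vo2 = NULL, body_mass = NULL) {
  convention <- match.arg(convention)
  if (convention == "rmr") {
    stop_if(any(tee < 0), "'tee' must be non-negative")
    return(tee / rmr_per_min(resting$rmr))
  }
  stop_if(is.null(vo2) || is.null(body_mass),
          "convention 'vo2_3.5' needs 'vo2' and 'body_mass'")
  (vo2 * 1000 / body_mass) / 3.5
}

#' Per-participant-per-task steady-state summaries
#'
#' Reduces the epoch and gas streams of a dataset to one row per completed
#' participant-task: criterion TEE (Weir over the final 2 min), PAEE, METs,
#' RER, mean HR, mean PAC, PCI (walking tasks; uses the participant's own
#' rest-task mean HR) and the number of epochs averaged.
#'
#' @param dataset A `paee_dataset` (from [simulate_dataset()] /
#'   [read_dataset()]).
#' @param window Averaging window, minutes.
#' @return A data frame of class `activity_summary`.
#' @export
#' @examples
#' ds <- simulate_dataset(noiseless_config(seed = 1))
#' head(summarize_activities(ds))
summarize_activities <- function(dataset, window = STEADY_WINDOW_MIN) {
  req <- c("id", "task", "t_s")
  stop_if(!all(req %in% names(dataset$epochs)) ||
            !all(c(req, "vo2_l_min", "vco2_l_min") %in% names(dataset$gas)),
          "dataset format error: epochs/gas must have columns ",
          paste(req, collapse = ", "), " (+ vo2_l_min, vco2_l_min in gas)")
  tasks <- dataset$config$tasks
  parts <- dataset$participants
  keys <- unique(dataset$epochs[, c("id", "task")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    id <- keys$id[i]; tk_name <- keys$task[i]
    tk <- tasks[[tk_name]]
    p <- parts[parts$id == id, ]
    ep <- dataset$epochs[dataset$epochs$id == id & dataset$epochs$task == tk_name, ]
    gs <- dataset$gas[dataset$gas$id == id & dataset$gas$task == tk_name, ]
    em <- steady_state_mean(ep, tk$duration, window)
    gm <- steady_state_mean(gs, tk$duration, window)
    tee <- weir_ee(gm$vo2_l_min, gm$vco2_l_min)
    data.frame(
      id = id, group = p$group, task = tk_name, velocity = tk$velocity,
      tee = tee,
      paee = suppressWarnings(compute_paee(tee, p)),
      mets = compute_mets(tee, p),
      rer = compute_rer(gm$vo2_l_min, gm$vco2_l_min),
      mean_hr = em$hr_bpm, mean_pac = em$pac_counts_min,
      n_epochs_averaged = em$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # PCI against the participant's own measured rest HR (profile rest_hr as
  # fallback when the rest stage is absent from the dataset)
  rest_hr <- setNames(out$mean_hr[out$task == "rest"], out$id[out$task == "rest"])
  hr0 <- ifelse(out$id %in% names(rest_hr), rest_hr[out$id],
                parts$rest_hr[match(out$id, parts$id)])
  out$pci <- ifelse(out$velocity > 0, pci(out$mean_hr, hr0, pmax(out$velocity, 1e-9)),
                    NA_real_)
  rownames(out) <- NULL
  class(out) <- c("activity_summary", "data.frame")
  out
}
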