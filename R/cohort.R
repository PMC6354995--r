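# Synthetic cohort generator.  Participants are drawn from group
# specifications; each participant-task pair yields a 30-s epoch stream of
# accelerometer counts (PAC) and heart rate, plus a matched gas-exchange
# stream (V̇O₂, V̇CO₂) whose final-2-min Weir energy expenditure encodes the
# intended criterion PAEE exactly.  Criterion PAEE is generated from the
# group's true model applied to the realized final-2-min sensor means, so
# calibration is identifiable (noiselessly exact, unbiased under noise).

EPOCH_S <- 30
STEADY_WINDOW_MIN <- 2

#' Generate a synthetic cohort
#'
#' Draws participant profiles (RMR, resting HR, body mass, economy factor)
#' from group specifications.  The economy factor is a mean-one lognormal
#' multiplier carrying between-subject variation in task energy cost.
#'
#' @param specs List of [group_spec] objects (default: the 9/10/9 reference
#'   groups).
#' @param seed Master seed; the cohort is a pure function of (specs, seed).
#' @param economy_sdlog sdlog of the mean-one lognormal economy factor.
#' @return A data frame of class `cohort` with columns `id`, `group`,
#'   `rmr`, `rest_hr`, `body_mass`, `economy_factor`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' table(cohort$group)
generate_cohort <- function(specs = default_group_specs(), seed = 1,
                            economy_sdlog = default_noise()$economy_sdlog) {
  stop_if(!length(specs), "'specs' must be a non-empty list of group_spec")
  lapply(specs, function(s)
    stop_if(!inherits(s, "group_spec"), "every spec must be a 'group_spec'"))
  pieces <- lapply(specs, function(s) {
    withr::with_seed(hash_seed(seed, "cohort", s$label), {
      n <- s$n
      draw_pos <- function(mean, sd, floor) {
        x <- rnorm(n, mean, sd)
        for (i in seq_len(100)) {
          bad <- x <= floor
          if (!any(bad)) break
          x[bad] <- rnorm(sum(bad), mean, sd)
        }
        x
      }
      rmr <- draw_pos(s$rmr_mean, s$rmr_sd, 500)
      rest_hr <- draw_pos(s$rest_hr_mean, s$rest_hr_sd, 30)
      mass <- draw_pos(s$body_mass_mean, s$body_mass_sd, 30)
      economy <- if (economy_sdlog > 0)
        exp(rnorm(n, -economy_sdlog^2 / 2, economy_sdlog)) else rep(1, n)
      data.frame(
        id = paste0(toupper(substr(s$label, 1, 1)), seq_len(n)),
        group = s$label, rmr = rmr, rest_hr = rest_hr, body_mass = mass,
        economy_factor = economy, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  out
}

#' Draw task completion for a cohort
#'
#' Independent Bernoulli draws per participant-task with the task's
#' per-group completion probability (rest is always completed).  In
#' monotone mode a participant failing one flat treadmill speed also fails
#' all faster flat speeds; gradient stages remain independent.
#'
#' @param cohort A [generate_cohort()] data frame.
#' @param tasks List of [task_spec] objects.
#' @param seed Master seed.
#' @param monotone Enforce dropout monotonicity across flat speeds.
#' @return A data frame with columns `id`, `task`, `completed`.
#' @export
apply_dropout <- function(cohort, tasks = default_task_battery(), seed = 1,
                          monotone = FALSE) {
  task_names <- vapply(tasks, `[[`, character(1), "name")
  velocity <- vapply(tasks, `[[`, numeric(1), "velocity")
  gradient <- vapply(tasks, `[[`, numeric(1), "gradient")
  flat_walk <- velocity > 0 & gradient == 0
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    id <- cohort$id[i]; grp <- cohort$group[i]
    probs <- vapply(tasks, completion_prob_for, numeric(1), group = grp)
    probs[velocity == 0] <- 1
    done <- withr::with_seed(hash_seed(seed, "dropout", id),
                             stats::runif(length(tasks)) < probs)
    if (monotone && any(flat_walk)) {
      ord <- order(velocity[flat_walk])
      done[flat_walk][ord] <- cumprod(done[flat_walk][ord]) > 0
    }
    data.frame(id = id, task = task_names, completed = done,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate one participant-task activity
#'
#' Produces a 30-s epoch stream (PAC, HR) and a matched gas-exchange stream
#' (V̇O₂, V̇CO₂, L·min⁻¹).  Steady-state PAC is the group-task target scaled
#' by the participant's economy factor; steady-state HR is the
#' participant's resting HR plus the economy-scaled group HR reserve for
#' the task.  Both follow an exponential approach (time constant
#' `noise$tau_s`) over the first 3 minutes and are stationary over the
#' final 2 minutes.  Criterion PAEE is the generating model evaluated at
#' the realized final-2-min means plus `tm$residual_sd` noise (rest: PAEE
#' is exactly 0); V̇O₂ solves the Weir relation at the group-task RER so
#' that calorimetry recovers the intended total energy expenditure.
#'
#' @param participant One cohort row (list or 1-row data frame).
#' @param task A [task_spec].
#' @param tm The group's [true_model].
#' @param target The matching [reference_targets()] row (fields `pac_mean`,
#'   `hr_mean`, `rer_mean`) plus the group's resting-HR target `hr_rest`.
#' @param noise Noise settings (see [default_noise()]).
#' @param seed Master seed (substream derived from id and task name).
#' @param completed If `FALSE` the participant dropped out: both streams
#'   are returned empty.
#' @return List with data frames `epochs` (`t_s`, `pac_counts_min`,
#'   `hr_bpm`) and `gas` (`t_s`, `vo2_l_min`, `vco2_l_min`); `t_s` is the
#'   epoch start time in seconds.
#' @export
simulate_activity <- function(participant, task, tm, target,
                              noise = default_noise(), seed = 1,
                              completed = TRUE) {
  stop_if(task$duration < 3, "'task' duration must be >= 3 min")
  empty <- list(
    epochs = data.frame(t_s = numeric(0), pac_counts_min = numeric(0),
                        hr_bpm = numeric(0)),
    gas = data.frame(t_s = numeric(0), vo2_l_min = numeric(0),
                     vco2_l_min = numeric(0)))
  if (!isTRUE(completed)) return(empty)

  p <- as.list(participant)
  withr::with_seed(hash_seed(seed, "activity", p$id, task$name), {
    is_rest <- task$velocity == 0 && task$gradient == 0
    econ <- p$economy_factor
    t_s <- seq(0, task$duration * 60 - EPOCH_S, by = EPOCH_S)
    t_end <- t_s + EPOCH_S
    window_start <- (task$duration - STEADY_WINDOW_MIN) * 60
    in_window <- t_s >= window_start
    ramp <- 1 - exp(-t_end / noise$tau_s)
    ramp[in_window] <- 1

    # steady-state sensor levels for this participant-task
    pac_ss <- if (is_rest) 0 else
      max(0, target$pac_mean * econ + rnorm(1, 0, noise$pac_sd))
    hr_ss <- p$rest_hr + (target$hr_mean - target$hr_rest) * econ +
      rnorm(1, 0, noise$hr_sd)

    pac <- pac_ss * ramp
    hr <- p$rest_hr + (hr_ss - p$rest_hr) * ramp
    if (!is_rest && noise$pac_epoch_sd > 0)
      pac <- pmax(0, pac + rnorm(length(pac), 0, noise$pac_epoch_sd))
    if (noise$hr_epoch_sd > 0)
      hr <- hr + rnorm(length(hr), 0, noise$hr_epoch_sd)

    # criterion energy from the generating model at the realized window means
    paee_ss <- if (is_rest) 0 else
      true_model_mean(tm, mean(pac[in_window]), mean(hr[in_window])) +
        rnorm(1, 0, tm$residual_sd)
    rmr_min <- p$rmr / 1440
    tee_ss <- paee_ss + rmr_min
    if (tee_ss < 0.05) {
      # a living participant cannot expend ~zero energy; truncate the
      # extreme lower tail of the residual draw
      warning("simulated TEE non-physiological for ", p$id, "/", task$name,
              "; floored at 0.05 kcal/min", call. = FALSE)
      tee_ss <- 0.05
    }
    denom <- 3.941 + 1.106 * target$rer_mean
    vo2_ss <- tee_ss / denom
    vo2_rest <- rmr_min / denom
    vo2 <- vo2_rest + (vo2_ss - vo2_rest) * ramp
    vco2 <- target$rer_mean * vo2

    list(epochs = data.frame(t_s = t_s, pac_counts_min = pac, hr_bpm = hr),
         gas = data.frame(t_s = t_s, vo2_l_min = vo2, vco2_l_min = vco2))
  })
}

#' Simulate a complete dataset
#'
#' Cohort, dropout, and per-participant-task epoch + gas streams under one
#' configuration.  The result is a pure function of the configuration
#' (including its seed).
#'
#' @param config A [run_config].
#' @return A list of class `paee_dataset`: `participants`, `completion`,
#'   `epochs`, `gas` (long data frames keyed by `id`, `task`) and `config`.
#' @export
#' @examples
#' ds <- simulate_dataset(run_config(seed = 1))
#' nrow(ds$participants)
simulate_dataset <- function(config = default_config()) {
  validate_config(config)
  cohort <- generate_cohort(config$groups, config$seed,
                            config$noise$economy_sdlog)
  completion <- apply_dropout(cohort, config$tasks, config$seed,
                              config$monotone_dropout)
  targets <- config$targets
  task_names <- vapply(config$tasks, `[[`, character(1), "name")
  rest_hr_target <- setNames(targets$hr_mean[targets$task == "rest"],
                             targets$group[targets$task == "rest"])
  epochs_list <- list(); gas_list <- list(); k <- 0
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    for (tk in config$tasks) {
      done <- completion$completed[completion$id == p$id &
                                     completion$task == tk$name]
      if (!isTRUE(done[1])) next
      tgt <- targets[targets$group == p$group & targets$task == tk$name, ]
      tgt$hr_rest <- rest_hr_target[[p$group]]
      streams <- simulate_activity(p, tk, config$models[[p$group]], tgt,
                                   config$noise, config$seed)
      k <- k + 1
      streams$epochs$id <- p$id; streams$epochs$task <- tk$name
      streams$gas$id <- p$id; streams$gas$task <- tk$name
      epochs_list[[k]] <- streams$epochs
      gas_list[[k]] <- streams$gas
    }
  }
  reorder <- function(df) df[, c("id", "task", setdiff(names(df),
                                                       c("id", "task")))]
  epochs <- reorder(do.call(rbind, epochs_list))
  gas <- reorder(do.call(rbind, gas_list))
  rownames(epochs) <- rownames(gas) <- NULL
  structure(list(participants = as.data.frame(cohort),
                 completion = completion, epochs = epochs, gas = gas,
                 config = config),
            class = "paee_dataset")
}

#' @export
print.paee_dataset <- function(x, ...) {
  cat("Synthetic PAEE dataset:", nrow(x$participants), "participants,",
      sum(x$completion$completed), "completed participant-tasks,",
      nrow(x$epochs), "epochs (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a dataset to delimited text files
#'
#' Emits `participants.tsv`, `epochs.tsv`, `gas.tsv`, `completion.tsv`, a
#' `config.yaml` key-value document and a `manifest.json` (seed, config
#' hash, record counts, package version).  Numeric values are written with
#' 15 significant digits so a read-back reproduces them to ~1e-15 relative.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param path Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(path), "cannot create output directory: ", path)
  files <- c(participants = "participants.tsv", epochs = "epochs.tsv",
             gas = "gas.tsv", completion = "completion.tsv")
  for (nm in names(files))
    write_tsv(dataset[[nm]], file.path(path, files[[nm]]))
  cfg <- dataset$config
  yaml::write_yaml(list(
    seed = cfg$seed,
    monotone_dropout = cfg$monotone_dropout,
    noise = cfg$noise,
    groups = lapply(cfg$groups, unclass),
    tasks = lapply(cfg$tasks, function(tk) {
      tk$completion_prob <- as.list(tk$completion_prob); unclass(tk)
    })), file.path(path, "config.yaml"))
  manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                   n_participants = nrow(dataset$participants),
                   n_epochs = nrow(dataset$epochs),
                   n_gas = nrow(dataset$gas),
                   package_version = as.character(packageVersion("paeecal")))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(path, c(files, "config.yaml", "manifest.json")))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path Directory containing the dataset files.
#' @return A `paee_dataset` list (config restored from `config.yaml`;
#'   targets/models are the package defaults it was written with).
#' @export
read_dataset <- function(path) {
  stop_if(!dir.exists(path), "no such dataset directory: ", path)
  y <- yaml::read_yaml(file.path(path, "config.yaml"))
  groups <- lapply(y$groups, function(g) do.call(group_spec, g))
  tasks <- lapply(y$tasks, function(tk) {
    tk$completion_prob <- unlist(tk$completion_prob) %||% numeric(0)
    do.call(task_spec, tk)
  })
  names(tasks) <- vapply(tasks, `[[`, character(1), "name")
  cfg <- run_config(seed = y$seed, groups = groups, tasks = tasks,
                    noise = y$noise, monotone_dropout = y$monotone_dropout)
  structure(list(
    participants = read_tsv(file.path(path, "participants.tsv")),
    completion = read_tsv(file.path(path, "completion.tsv")),
    epochs = read_tsv(file.path(path, "epochs.tsv")),
    gas = read_tsv(file.path(path, "gas.tsv")),
    config = cfg), class = "paee_dataset")
}
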