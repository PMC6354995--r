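# Cohort configuration objects: group specifications, task specifications,
# generating ("true") models, noise settings, and the run configuration that
# bundles them.  Constructors validate; defaults reproduce the reference
# study conditions.

#' Define a participant group
#'
#' @param label Group label: `"unilateral"`, `"bilateral"` or `"control"`.
#' @param n Number of participants (>= 1).
#' @param rmr_mean,rmr_sd Resting metabolic rate, kcal·day⁻¹ (mean > 0, sd >= 0).
#' @param rest_hr_mean,rest_hr_sd Resting heart rate, bpm; mean must lie in
#'   (30, 120).
#' @param body_mass_mean,body_mass_sd Body mass, kg.
#' @return An object of class `group_spec`.
#' @export
#' @examples
#' group_spec("control", 9, 1846, 191, 54, 4, 80, 7)
group_spec <- function(label, n, rmr_mean, rmr_sd, rest_hr_mean, rest_hr_sd,
                       body_mass_mean, body_mass_sd) {
  label <- match.arg(label, c("unilateral", "bilateral", "control"))
  stop_if(length(n) != 1 || is.na(n) || n < 1 || n != round(n),
          "'n' must be a positive integer")
  sds <- c(rmr_sd = rmr_sd, rest_hr_sd = rest_hr_sd, body_mass_sd = body_mass_sd)
  stop_if(any(sds < 0), "standard deviations must be >= 0: ",
          paste(names(sds)[sds < 0], collapse = ", "))
  stop_if(rmr_mean <= 0, "'rmr_mean' must be > 0")
  stop_if(rest_hr_mean <= 30 || rest_hr_mean >= 120,
          "'rest_hr_mean' must lie in (30, 120) bpm")
  stop_if(body_mass_mean <= 0, "'body_mass_mean' must be > 0")
  structure(list(label = label, n = as.integer(n),
                 rmr_mean = rmr_mean, rmr_sd = rmr_sd,
                 rest_hr_mean = rest_hr_mean, rest_hr_sd = rest_hr_sd,
                 body_mass_mean = body_mass_mean, body_mass_sd = body_mass_sd),
            class = "group_spec")
}

#' Define a protocol task
#'
#' @param name Task name.
#' @param velocity Treadmill velocity, m·s⁻¹ (0 for rest).
#' @param gradient Treadmill gradient, % (default 0).
#' @param duration Stage duration, minutes (default 5).
#' @param completion_prob Named numeric vector of per-group completion
#'   probabilities in \[0, 1\]; groups not named default to 1.
#' @return An object of class `task_spec`.
#' @export
#' @examples
#' task_spec("walk_1.34", 1.34, completion_prob = c(bilateral = 0.2))
task_spec <- function(name, velocity, gradient = 0, duration = 5,
                      completion_prob = numeric(0)) {
  stop_if(velocity < 0, "'velocity' must be >= 0")
  stop_if(duration <= 0, "'duration' must be > 0")
  stop_if(length(completion_prob) &&
            (any(completion_prob < 0) || any(completion_prob > 1)),
          "'completion_prob' entries must lie in [0, 1]")
  structure(list(name = name, velocity = velocity, gradient = gradient,
                 duration = duration, completion_prob = completion_prob),
            class = "task_spec")
}

completion_prob_for <- function(task, group) {
  p <- task$completion_prob
  if (length(p) && group %in% names(p)) unname(p[[group]]) else 1
}

#' Define a generating model for the synthetic cohort
#'
#' The model `PAEE = intercept + beta_pac * PAC + beta_hr * HR + e`,
#' `e ~ N(0, residual_sd²)`, used to generate criterion PAEE from the
#' simulated sensor streams.
#'
#' @param beta_pac kcal·min⁻¹ per count·min⁻¹.
#' @param beta_hr kcal·min⁻¹ per bpm.
#' @param intercept kcal·min⁻¹.
#' @param residual_sd Residual SD, kcal·min⁻¹ (>= 0).
#' @param group Group label the model belongs to.
#' @return An object of class `true_model`.
#' @export
true_model <- function(beta_pac, beta_hr, intercept, residual_sd = 0,
                       group = NA_character_) {
  stop_if(residual_sd < 0, "'residual_sd' must be >= 0")
  structure(list(beta_pac = beta_pac, beta_hr = beta_hr,
                 intercept = intercept, residual_sd = residual_sd,
                 group = group),
            class = "true_model")
}

true_model_mean <- function(tm, pac, hr) {
  tm$intercept + tm$beta_pac * pac + tm$beta_hr * hr
}

#' Default group specifications
#'
#' The three reference groups ([reference_groups()]) as `group_spec`
#' objects.
#' @return Named list of [group_spec] objects.
#' @export
default_group_specs <- function() {
  g <- reference_groups()
  out <- lapply(seq_len(nrow(g)), function(i) {
    group_spec(g$group[i], g$n[i], g$rmr_mean[i], g$rmr_sd[i],
               g$rest_hr_mean[i], g$rest_hr_sd[i],
               g$body_mass_mean[i], g$body_mass_sd[i])
  })
  names(out) <- g$group
  out
}

#' Default task battery
#'
#' The reference protocol ([reference_tasks()]) as `task_spec` objects,
#' with per-group completion probabilities equal to the published
#' completers-to-group-size ratios (e.g. 2/10 for the bilateral group at
#' 1.34 m·s⁻¹).
#' @return Named list of [task_spec] objects.
#' @export
default_task_battery <- function() {
  tasks <- reference_tasks()
  targets <- reference_targets()
  groups <- reference_groups()
  out <- lapply(seq_len(nrow(tasks)), function(i) {
    tk <- tasks$task[i]
    tg <- targets[targets$task == tk, ]
    p <- setNames(tg$n_completed / groups$n[match(tg$group, groups$group)],
                  tg$group)
    task_spec(tk, tasks$velocity[i], tasks$gradient[i], tasks$duration[i],
              completion_prob = p)
  })
  names(out) <- tasks$task
  out
}

#' Default generating models
#'
#' The published equations ([printed_models()]) with residual SDs set to the
#' published SEE of the GT3X+HR fits (0.78, 0.96, 0.48 kcal·min⁻¹).
#' @return Named list of [true_model] objects.
#' @export
default_true_models <- function() {
  coefs <- printed_coefficients()
  see <- c(unilateral = 0.78, bilateral = 0.96, control = 0.48)
  out <- lapply(names(coefs), function(g) {
    k <- coefs[[g]]
    true_model(beta_pac = k[["pac"]], beta_hr = k[["hr"]],
               intercept = k[["intercept"]], residual_sd = see[[g]],
               group = g)
  })
  names(out) <- names(coefs)
  out
}

#' Default noise settings
#'
#' Between-subject variation enters through a mean-one lognormal economy
#' factor (sdlog 0.15); task-level realisation noise on steady-state PAC
#' (400 counts·min⁻¹) and HR (6 bpm); epoch-level jitter (25 counts·min⁻¹,
#' 1.5 bpm); and a 45 s time constant for the exponential approach to
#' steady state.
#' @return Named list of noise parameters.
#' @export
default_noise <- function() {
  list(economy_sdlog = 0.15, pac_sd = 400, hr_sd = 6,
       pac_epoch_sd = 25, hr_epoch_sd = 1.5, tau_s = 45)
}

zero_noise <- function() {
  list(economy_sdlog = 0, pac_sd = 0, hr_sd = 0,
       pac_epoch_sd = 0, hr_epoch_sd = 0, tau_s = 45)
}

#' Run configuration
#'
#' Bundles everything a simulation run depends on.  The defaults reproduce
#' the reference study conditions: group sizes 9/10/9, the 8-task treadmill
#' battery, published group-task targets, published equations as generating
#' models, and the default noise settings.
#'
#' @param seed Master seed; all substreams derive from it.
#' @param groups List of [group_spec] objects.
#' @param tasks List of [task_spec] objects.
#' @param models Named list of [true_model] objects (one per group label).
#' @param targets Group-by-task target table (see [reference_targets()]).
#' @param noise Noise settings (see [default_noise()]).
#' @param monotone_dropout If `TRUE`, a participant failing one treadmill
#'   speed fails all faster speeds.
#' @return An object of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config(seed = 7)
#' cfg$groups$control$n
run_config <- function(seed = 1,
                       groups = default_group_specs(),
                       tasks = default_task_battery(),
                       models = default_true_models(),
                       targets = reference_targets(),
                       noise = default_noise(),
                       monotone_dropout = FALSE) {
  cfg <- structure(list(seed = as.integer(seed), groups = groups,
                        tasks = tasks, models = models, targets = targets,
                        noise = noise,
                        monotone_dropout = isTRUE(monotone_dropout)),
                   class = "run_config")
  validate_config(cfg)
  cfg
}

#' @rdname run_config
#' @export
default_config <- function(seed = 1) run_config(seed = seed)

#' Noise-free run configuration
#'
#' All noise terms zero and completion probabilities one: every simulated
#' record lies exactly on the generating model, so downstream fits recover
#' its coefficients to machine precision.
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
noiseless_config <- function(seed = 1) {
  tasks <- lapply(default_task_battery(), function(tk) {
    tk$completion_prob <- numeric(0)
    tk
  })
  models <- lapply(default_true_models(), function(tm) {
    tm$residual_sd <- 0
    tm
  })
  run_config(seed = seed, tasks = tasks, models = models,
             noise = zero_noise())
}

validate_config <- function(cfg) {
  bad <- character(0)
  if (!is.list(cfg$groups) || !length(cfg$groups) ||
      !all(vapply(cfg$groups, inherits, logical(1), "group_spec")))
    bad <- c(bad, "groups (list of group_spec)")
  if (!is.list(cfg$tasks) || !length(cfg$tasks) ||
      !all(vapply(cfg$tasks, inherits, logical(1), "task_spec")))
    bad <- c(bad, "tasks (list of task_spec)")
  if (length(bad) == 0) {
    labels <- vapply(cfg$groups, `[[`, character(1), "label")
    if (!all(labels %in% names(cfg$models)))
      bad <- c(bad, "models (missing group label)")
    need <- expand.grid(group = labels,
                        task = vapply(cfg$tasks, `[[`, character(1), "name"),
                        stringsAsFactors = FALSE)
    have <- paste(cfg$targets$group, cfg$targets$task)
    if (!all(paste(need$group, need$task) %in% have))
      bad <- c(bad, "targets (missing group-task rows)")
  }
  noise_keys <- c("economy_sdlog", "pac_sd", "hr_sd", "pac_epoch_sd",
                  "hr_epoch_sd", "tau_s")
  if (!all(noise_keys %in% names(cfg$noise)))
    bad <- c(bad, paste0("noise (needs ",
                         paste(setdiff(noise_keys, names(cfg$noise)),
                               collapse = ", "), ")"))
  stop_if(length(bad) > 0,
          "invalid configuration; offending keys: ",
          paste(bad, collapse = "; "))
  invisible(cfg)
}

config_hash <- function(cfg) {
  hash_seed(paste(deparse(unclass(cfg)), collapse = "\n"))
}
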