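# Reference constants from the source validation study: group demographics,
# the treadmill task battery, group-by-task steady-state targets, the three
# published prediction equations, and the published agreement table.  These
# are both fixtures (the synthetic cohort reproduces them) and the inputs to
# the worked-example checks.

#' Reference group demographics
#'
#' Population parameters for the three study groups: unilateral lower-limb
#' amputees (n = 9), bilateral amputees (n = 10) and non-injured physically
#' active controls (n = 9).  RMR is resting metabolic rate (kcal·day⁻¹),
#' resting heart rate is the semi-recumbent rest value (bpm), body mass in
#' kg; all as mean and SD.
#'
#' @return A data frame with one row per group.
#' @export
#' @examples
#' reference_groups()
reference_groups <- function() {
  data.frame(
    group         = c("unilateral", "bilateral", "control"),
    n             = c(9L, 10L, 9L),
    rmr_mean      = c(1776, 1596, 1846),
    rmr_sd        = c(269, 178, 191),
    rest_hr_mean  = c(66, 67, 54),
    rest_hr_sd    = c(11, 10, 4),
    body_mass_mean = c(81, 82, 80),
    body_mass_sd  = c(11, 19, 7),
    stringsAsFactors = FALSE
  )
}

#' Reference task battery
#'
#' The laboratory protocol: semi-recumbent rest, five progressive treadmill
#' velocities (0.48, 0.67, 0.89, 1.12, 1.34 m·s⁻¹) and two gradients (3 %
#' and 5 %) at 0.89 m·s⁻¹, each stage lasting 5 minutes.
#'
#' @return A data frame with columns `task`, `velocity` (m·s⁻¹, 0 for
#'   rest), `gradient` (%), `duration` (min).
#' @export
reference_tasks <- function() {
  data.frame(
    task     = c("rest", "walk_0.48", "walk_0.67", "walk_0.89", "walk_1.12",
                 "walk_1.34", "incline_3pct", "incline_5pct"),
    velocity = c(0, 0.48, 0.67, 0.89, 1.12, 1.34, 0.89, 0.89),
    gradient = c(0, 0, 0, 0, 0, 0, 3, 5),
    duration = 5,
    stringsAsFactors = FALSE
  )
}

#' Reference group-by-task steady-state targets
#'
#' Published group means (and SDs) of criterion PAEE (kcal·min⁻¹),
#' accelerometer output (PAC, counts·min⁻¹), heart rate (bpm), respiratory
#' exchange ratio and physiological cost index (beats·m⁻¹) for every
#' group-task combination, together with the number of participants who
#' completed each task.  These targets parameterise the synthetic cohort
#' and drive the worked-example checks.
#'
#' @return A data frame with one row per group-task combination.
#' @export
#' @examples
#' subset(reference_targets(), group == "control")
reference_targets <- function() {
  tasks <- reference_tasks()$task
  out <- rbind(
    data.frame(
      group = "unilateral", task = tasks,
      paee_mean = c(0, 2.40, 3.00, 3.61, 4.39, 5.89, 4.17, 4.82),
      paee_sd   = c(0, 0.71, 0.95, 1.12, 1.42, 1.70, 1.06, 1.24),
      pac_mean  = c(0, 2643, 2939, 3353, 4107, 4977, 3642, 4020),
      pac_sd    = c(0, 866, 908, 892, 707, 581, 981, 1005),
      hr_mean   = c(66, 96, 101, 106, 112, 126, 111, 119),
      hr_sd     = c(11, 17, 18, 21, 24, 36, 21, 23),
      rer_mean  = c(0.74, 0.76, 0.79, 0.81, 0.83, 0.86, 0.82, 0.84),
      rer_sd    = c(0.04, 0.04, 0.04, 0.03, 0.03, 0.05, 0.04, 0.04),
      pci_mean  = c(NA, 1.01, 0.85, 0.74, 0.67, 0.73, 0.84, 0.99),
      pci_sd    = c(NA, 0.28, 0.24, 0.26, 0.26, 0.33, 0.26, 0.29),
      n_completed = c(9L, 9L, 9L, 9L, 9L, 6L, 9L, 9L),
      stringsAsFactors = FALSE
    ),
    data.frame(
      group = "bilateral", task = tasks,
      paee_mean = c(0, 3.72, 4.59, 5.46, 5.54, 5.23, 5.93, 5.77),
      paee_sd   = c(0, 1.37, 1.54, 1.74, 2.85, 2.76, 2.29, 1.85),
      pac_mean  = c(0, 4800, 5264, 5600, 6123, 5235, 5973, 5806),
      pac_sd    = c(0, 1410, 1603, 1502, 2823, 1212, 1592, 2231),
      hr_mean   = c(67, 108, 121, 133, 139, 142, 138, 146),
      hr_sd     = c(10, 13, 15, 18, 31, 41, 19, 30),
      rer_mean  = c(0.75, 0.78, 0.81, 0.84, 0.91, 0.86, 0.87, 0.93),
      rer_sd    = c(0.04, 0.03, 0.04, 0.05, 0.18, 0.07, 0.07, 0.17),
      pci_mean  = c(NA, 1.45, 1.35, 1.25, 1.22, 1.03, 1.36, 1.37),
      pci_sd    = c(NA, 0.32, 0.29, 0.32, 0.43, 0.36, 0.40, 0.56),
      n_completed = c(10L, 10L, 10L, 10L, 3L, 2L, 8L, 4L),
      stringsAsFactors = FALSE
    ),
    data.frame(
      group = "control", task = tasks,
      paee_mean = c(0, 1.43, 1.81, 2.32, 2.80, 3.40, 2.88, 3.45),
      paee_sd   = c(0, 0.31, 0.32, 0.40, 0.43, 0.34, 0.38, 0.43),
      pac_mean  = c(0, 1299, 1811, 2430, 3325, 4144, 2551, 2720),
      pac_sd    = c(0, 411, 368, 459, 480, 457, 385, 311),
      hr_mean   = c(54, 72, 74, 78, 82, 85, 83, 87),
      hr_sd     = c(4, 7, 6, 4, 5, 5, 5, 4),
      rer_mean  = c(0.75, 0.78, 0.82, 0.82, 0.82, 0.83, 0.84, 0.83),
      rer_sd    = c(0.04, 0.03, 0.04, 0.05, 0.03, 0.04, 0.04, 0.04),
      pci_mean  = c(NA, 0.61, 0.50, 0.45, 0.41, 0.38, 0.54, 0.61),
      pci_sd    = c(NA, 0.15, 0.09, 0.05, 0.04, 0.04, 0.06, 0.06),
      n_completed = c(9L, 9L, 9L, 9L, 9L, 9L, 9L, 9L),
      stringsAsFactors = FALSE
    )
  )
  rownames(out) <- NULL
  out
}

# Published GT3X+HR equation coefficients per group.
printed_coefficients <- function() {
  list(
    unilateral = c(intercept = -2.713284, pac = 0.000453, hr = 0.045487),
    bilateral  = c(intercept = -1.795157, pac = 0.000658, hr = 0.025308),
    control    = c(intercept = -1.797866, pac = 0.000550, hr = 0.036472)
  )
}

#' Published PAEE prediction equations
#'
#' The three population-specific GT3X+HR equations,
#' `PAEE = intercept + beta_pac * PAC + beta_hr * HR`, shipped as immutable
#' model fixtures.  Their diagnostics slots carry the published r, R² and
#' SEE for the GT3X+HR method (the publication's own fit statistics; n is
#' unknown and stored as `NA`).
#'
#' @return A named list of [paee_model] objects
#'   (`unilateral`, `bilateral`, `control`).
#' @seealso [fit_paee_model()], [predict_paee()]
#' @export
#' @examples
#' printed_models()$unilateral
printed_models <- function() {
  coefs <- printed_coefficients()
  agree <- reference_agreement()
  agree <- agree[agree$method == "gt3x_hr", ]
  out <- lapply(names(coefs), function(g) {
    row <- agree[agree$group == g, ]
    new_paee_model(coefs[[g]], predictors = c("pac", "hr"), group = g,
                   r = row$r, r_squared = row$r_squared, see = row$see,
                   n = NA_integer_, source = "printed")
  })
  names(out) <- names(coefs)
  out
}

#' Published agreement statistics
#'
#' The published validity statistics per group and method over treadmill
#' walking: Pearson r, R², standard error of the estimate (kcal·min⁻¹),
#' mean bias and 95 % limits-of-agreement half-width (kcal·min⁻¹).
#' Methods: `gt3x_hr` (accelerometer + heart-rate equation), `hr_only`
#' (heart rate alone), `actiheart` (the proprietary multi-sensor device,
#' treated throughout as an externally supplied prediction series).
#'
#' @return A data frame with one row per group-method combination.
#' @export
reference_agreement <- function() {
  data.frame(
    group  = rep(c("unilateral", "bilateral", "control"), each = 3),
    method = rep(c("gt3x_hr", "hr_only", "actiheart"), times = 3),
    r         = c(0.92, 0.89, 0.86, 0.93, 0.88, 0.81, 0.91, 0.84, 0.67),
    r_squared = c(0.85, 0.79, 0.73, 0.87, 0.77, 0.65, 0.83, 0.71, 0.45),
    see       = c(0.78, 0.91, 1.02, 0.96, 1.26, 1.53, 0.48, 0.62, 0.85),
    bias      = c(0, 0, -1.40, 0, 0, 0.21, 0, 0, 0.29),
    loa_half_width = c(1.50, 1.77, 2.00, 1.84, 2.44, 4.28, 0.93, 1.82, 1.82),
    stringsAsFactors = FALSE
  )
}
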