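# Pipeline orchestration: simulate -> summarize -> calibrate ->
# cross-validate -> agree, plus the embedded worked-example checks.

#' Simulate a dataset (pipeline stage)
#'
#' Thin wrapper over [simulate_dataset()] that optionally writes the
#' dataset (with config and manifest) to a directory.
#'
#' @param config A [run_config].
#' @param out Optional output directory for [write_dataset()].
#' @return The `paee_dataset`, invisibly if written to disk.
#' @export
run_simulate <- function(config = default_config(), out = NULL) {
  ds <- simulate_dataset(config)
  if (!is.null(out)) {
    write_dataset(ds, out)
    return(invisible(ds))
  }
  ds
}

#' Validate prediction methods on a dataset
#'
#' Per group, compares criterion PAEE (final-2-min Weir calorimetry minus
#' RMR) against:
#' \describe{
#'   \item{fitted}{the group's own PAC+HR equation under
#'     leave-one-participant-out cross-validation (out-of-sample);}
#'   \item{printed}{the published fixture equations applied directly;}
#'   \item{hr_only}{an HR-only linear comparator, also under LOOCV;}
#'   \item{external}{any externally supplied prediction column (e.g. a
#'     proprietary multi-sensor device), joined by participant and task.}
#' }
#' Emits a task-level summary table, the fitted models, the prediction
#' pairs, an agreement table (r, R², SEE, bias, LoA) and per-task error
#' tables (MAE, MAPE, signed error, RMSE).
#'
#' @param dataset A `paee_dataset`.
#' @param methods Subset of `c("fitted", "printed", "hr_only")`.
#' @param external Optional data frame `participant`, `task`, `predicted`.
#' @param clamp_zero Floor model predictions at zero.
#' @return A list of class `paee_report`.
#' @export
#' @examples
#' rep <- run_validate(run_simulate(noiseless_config(1)))
#' subset(rep$agreement, method == "fitted")
run_validate <- function(dataset,
                         methods = c("fitted", "printed", "hr_only"),
                         external = NULL, clamp_zero = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  summaries <- summarize_activities(dataset)
  records <- build_records(summaries)
  groups <- unique(records$group)
  models <- list()
  pred_rows <- list()

  collect <- function(rec, predicted, group, method, fold = NA_integer_) {
    data.frame(participant = rec$participant, group = group,
               task = rec$task, criterion = rec$criterion_paee,
               predicted = predicted, method = method, fold = fold,
               stringsAsFactors = FALSE)
  }
  for (g in groups) {
    rec <- records[records$group == g, ]
    if ("fitted" %in% methods) {
      models[[g]] <- fit_paee_model(rec)
      cv <- loocv_predict(rec)
      pred <- if (clamp_zero) pmax(cv$predicted, 0) else cv$predicted
      pred_rows[[paste(g, "fitted")]] <- collect(rec, pred, g, "fitted",
                                                 cv$fold)
    }
    if ("printed" %in% methods) {
      m <- printed_models()[[g]]
      pred_rows[[paste(g, "printed")]] <-
        collect(rec, predict_paee(m, rec$pac, rec$hr, clamp_zero), g,
                "printed")
    }
    if ("hr_only" %in% methods) {
      cv <- loocv_predict(rec, predictors = "hr")
      pred <- if (clamp_zero) pmax(cv$predicted, 0) else cv$predicted
      pred_rows[[paste(g, "hr_only")]] <- collect(rec, pred, g, "hr_only",
                                                  cv$fold)
    }
  }
  if (!is.null(external)) {
    stop_if(!all(c("participant", "task", "predicted") %in% names(external)),
            "'external' must have columns participant, task, predicted")
    for (g in groups) {
      rec <- records[records$group == g, ]
      m <- match(paste(rec$participant, rec$task),
                 paste(external$participant, external$task))
      keep <- !is.na(m)
      if (!any(keep)) next
      pred_rows[[paste(g, "external")]] <-
        collect(rec[keep, ], external$predicted[m[keep]], g, "external")
    }
  }
  predictions <- do.call(rbind, pred_rows)
  rownames(predictions) <- NULL

  key <- interaction(predictions$group, predictions$method, drop = TRUE)
  agreement <- do.call(rbind, lapply(split(predictions, key), function(d) {
    ok <- !is.na(d$predicted)
    n_params <- if (d$method[1] == "hr_only") 2 else 3
    rep <- agreement_report(d$criterion[ok], d$predicted[ok], n_params)
    data.frame(group = d$group[1], method = d$method[1],
               r = rep$r, r_squared = rep$r_squared, see = rep$see,
               bias = rep$bias, loa_half_width = rep$loa_half_width,
               n = rep$n, stringsAsFactors = FALSE)
  }))
  rownames(agreement) <- NULL

  errors <- do.call(rbind, lapply(split(predictions, key), function(d) {
    ok <- !is.na(d$predicted)
    et <- error_stats(data.frame(task = d$task[ok],
                                 criterion = d$criterion[ok],
                                 predicted = d$predicted[ok]))
    cbind(group = d$group[1], method = d$method[1], et,
          stringsAsFactors = FALSE)
  }))
  rownames(errors) <- NULL

  structure(list(summaries = summaries, pci = pci_table(summaries),
                 models = models, predictions = predictions,
                 agreement = agreement, errors = errors,
                 seed = dataset$config$seed,
                 config_hash = config_hash(dataset$config)),
            class = "paee_report")
}

#' @export
print.paee_report <- function(x, ...) {
  cat("PAEE validation report (seed", x$seed, ")\n\nAgreement:\n")
  print(format(x$agreement, digits = 3))
  invisible(x)
}

#' Write a report bundle to delimited text files
#'
#' `summaries.tsv`, `pci.tsv`, `models.txt` (key-value), `predictions.tsv`,
#' `agreement.tsv`, `errors.tsv` and `manifest.json` (seed, config hash,
#' package version, record counts).
#'
#' @param report A [run_validate()] result.
#' @param path Output directory.
#' @return Invisibly, the files written.
#' @export
write_report_bundle <- function(report, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(path), "cannot create output directory: ", path)
  tabs <- c("summaries", "pci", "predictions", "agreement", "errors")
  for (nm in tabs)
    write_tsv(as.data.frame(report[[nm]]), file.path(path, paste0(nm, ".tsv")))
  lines <- unlist(lapply(names(report$models), function(g) {
    m <- report$models[[g]]
    c(paste0("[", g, "]"),
      vapply(names(m$coefficients), function(k)
        sprintf("%s = %.12g", k, m$coefficients[[k]]), character(1)),
      sprintf("r = %.12g", m$r), sprintf("r_squared = %.12g", m$r_squared),
      sprintf("see = %.12g", m$see), sprintf("n = %d", m$n), "")
  }))
  writeLines(lines, file.path(path, "models.txt"))
  jsonlite::write_json(
    list(seed = report$seed, config_hash = report$config_hash,
         package_version = as.character(packageVersion("paeecal")),
         n_summaries = nrow(report$summaries),
         n_predictions = nrow(report$predictions)),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(path, c(paste0(tabs, ".tsv"), "models.txt",
                              "manifest.json")))
}

#' Recompute the embedded reference-table checks
#'
#' Every check uses only constants embedded in the package (the reference
#' tables and published equations): applying each group's equation to its
#' group-task means, group-mean absolute percentage errors against the
#' published cross-validation error bounds, PCI and METs reconstructions,
#' between-group HR-ratio bands, and the design sample-size computation.
#'
#' @param format `"data.frame"` (default) or `"json"`.
#' @param ids Optional character vector to select individual checks.
#' @param quiet Suppress the printed pass/fail table.
#' @return Data frame `id`, `description`, `value`, `expected`, `cmp`,
#'   `tolerance`, `pass` (or its JSON rendering), invisibly when printed.
#' @export
#' @examples
#' checks <- run_worked_examples(quiet = TRUE)
#' all(checks$pass)
run_worked_examples <- function(format = c("data.frame", "json"),
                                ids = NULL, quiet = FALSE) {
  format <- match.arg(format)
  tg <- reference_targets()
  walk <- tg[tg$task != "rest", ]
  eqs <- printed_models()
  checks <- list()
  add <- function(id, description, value, expected, cmp = "eq",
                  tolerance = 0) {
    pass <- switch(cmp,
                   eq = abs(value - expected) <= tolerance,
                   le = value <= expected,
                   ge = value >= expected)
    checks[[length(checks) + 1]] <<- data.frame(
      id = id, description = description, value = value,
      expected = expected, cmp = cmp, tolerance = tolerance, pass = pass,
      stringsAsFactors = FALSE)
  }

  # published equations applied to their own group-task means
  uni089 <- walk[walk$group == "unilateral" & walk$task == "walk_0.89", ]
  add("eq_uni_0.89",
      "unilateral equation at 0.89 m/s group means vs criterion PAEE",
      predict_paee(eqs$unilateral, uni089$pac_mean, uni089$hr_mean),
      uni089$paee_mean, tolerance = 0.01 * uni089$paee_mean)
  mape_bounds <- c(unilateral = 18, bilateral = 15, control = 15)
  for (g in names(mape_bounds)) {
    d <- walk[walk$group == g, ]
    pred <- predict_paee(eqs[[g]], d$pac_mean, d$hr_mean)
    add(paste0("mape_", g),
        paste0(g, " equation MAPE over walking-task means, vs published ",
               "LOOCV percent error"),
        mean(abs(pred - d$paee_mean) / d$paee_mean) * 100,
        unname(mape_bounds[g]), cmp = "le")
  }

  # PCI reconstructions from group means
  rest_hr <- setNames(tg$hr_mean[tg$task == "rest"],
                      tg$group[tg$task == "rest"])
  pci_checks <- list(c("unilateral", "walk_0.89", 0.74),
                     c("control", "walk_1.34", 0.38))
  for (pc in pci_checks) {
    d <- walk[walk$group == pc[1] & walk$task == pc[2], ]
    add(paste0("pci_", pc[1], "_", d$task),
        paste0("PCI from ", pc[1], " group means at ",
               reference_tasks()$velocity[reference_tasks()$task == pc[2]],
               " m/s vs published value"),
        pci(d$hr_mean, rest_hr[[pc[1]]],
            reference_tasks()$velocity[reference_tasks()$task == pc[2]]),
        as.numeric(pc[3]), tolerance = 0.02 * as.numeric(pc[3]))
  }

  # METs reconstructions
  gref <- reference_groups()
  add("mets_rest", "RMR-referenced METs at rest (exact by construction)",
      compute_mets(rmr_per_min(1596), list(rmr = 1596)), 1.0)
  bil048 <- walk[walk$group == "bilateral" & walk$task == "walk_0.48", ]
  rmr_bil <- gref$rmr_mean[gref$group == "bilateral"]
  add("mets_bilateral_0.48",
      "bilateral METs at 0.48 m/s from group-mean PAEE and RMR",
      compute_mets(bil048$paee_mean + rmr_per_min(rmr_bil),
                   list(rmr = rmr_bil)),
      4.4, tolerance = 0.01 * 4.4)

  # between-group HR-ratio bands
  hr_tab <- function(g, tasks) data.frame(
    task = tasks, mean_hr = tg$hr_mean[match(paste(g, tasks),
                                             paste(tg$group, tg$task))])
  all_walk <- walk$task[walk$group == "unilateral"]
  restricted <- c("walk_0.48", "walk_0.67", "walk_0.89", "incline_3pct")
  uc <- between_group_hr_ratio(hr_tab("unilateral", all_walk),
                               hr_tab("control", all_walk))$range
  add("hr_ratio_uni_ctl_min", "unilateral/control HR ratio lower bound",
      uc[1], 1.3, cmp = "ge")
  add("hr_ratio_uni_ctl_max", "unilateral/control HR ratio upper bound",
      uc[2], 1.5, cmp = "le")
  bc <- between_group_hr_ratio(hr_tab("bilateral", restricted),
                               hr_tab("control", restricted))$range
  add("hr_ratio_bil_ctl_min",
      "bilateral/control HR ratio lower bound at restricted speeds",
      bc[1], 1.5, cmp = "ge")
  bu <- between_group_hr_ratio(hr_tab("bilateral", restricted),
                               hr_tab("unilateral", restricted))$range
  add("hr_ratio_bil_uni_max",
      "bilateral/unilateral HR ratio upper bound at restricted speeds",
      bu[2], 1.3, cmp = "le")

  # design sample size
  add("power_n", "paired sample size at d = 1.0, alpha = 0.05, power = 0.8",
      power_sample_size(d = 1.0, alpha = 0.05, power = 0.8), 8)

  out <- do.call(rbind, checks)
  if (!is.null(ids)) out <- out[out$id %in% ids, ]
  if (!quiet) {
    show <- out
    show$value <- signif(show$value, 6)
    print(show[, c("id", "value", "expected", "cmp", "pass")],
          row.names = FALSE)
  }
  if (format == "json")
    return(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA))
  if (quiet) out else invisible(out)
}
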