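# Gait economy metrics: physiological cost index and between-group heart
# rate comparisons.

#' Physiological cost index
#'
#' `PCI = (mean working HR - mean resting HR) / velocity (m·min⁻¹)`,
#' in beats per metre, using pre-set treadmill velocities.  Negative values
#' (working HR below rest) are flagged with a warning, not clipped.
#'
#' @param hr_work Mean working heart rate, bpm.
#' @param hr_rest Mean resting heart rate, bpm.
#' @param velocity Walking velocity, m·s⁻¹ (> 0; PCI is undefined at rest).
#' @return PCI, beats·m⁻¹.
#' @export
#' @examples
#' pci(106, 66, 0.89)   # 0.749 beats/m
pci <- function(hr_work, hr_rest, velocity) {
  stop_if(any(velocity <= 0), "PCI undefined: 'velocity' must be > 0")
  out <- (hr_work - hr_rest) / (velocity * 60)
  if (any(out < 0))
    warning("negative PCI (working HR below resting HR)", call. = FALSE)
  out
}

#' Between-group heart-rate ratios
#'
#' Per-task ratio of mean working HR between two groups, with its range.
#' Input tables need columns `task` and `mean_hr` (e.g. subsets of
#' [reference_targets()] with `hr_mean` renamed, or grouped
#' [summarize_activities()] output).
#'
#' @param a,b Data frames with columns `task`, `mean_hr`; `a` is the
#'   numerator group.
#' @param tasks Optional character vector restricting the comparison.
#' @return List with `ratios` (data frame `task`, `ratio`) and `range`
#'   (`c(min, max)`).
#' @export
#' @examples
#' tg <- reference_targets()
#' uni <- data.frame(task = tg$task[tg$group == "unilateral"],
#'                   mean_hr = tg$hr_mean[tg$group == "unilateral"])
#' ctl <- data.frame(task = tg$task[tg$group == "control"],
#'                   mean_hr = tg$hr_mean[tg$group == "control"])
#' between_group_hr_ratio(uni, ctl, tasks = "walk_1.34")$ratios
between_group_hr_ratio <- function(a, b, tasks = NULL) {
  if (is.null(tasks)) tasks <- intersect(a$task, b$task)
  missing_a <- setdiff(tasks, a$task)
  missing_b <- setdiff(tasks, b$task)
  stop_if(length(missing_a) || length(missing_b),
          "task(s) missing from a group: ",
          paste(unique(c(missing_a, missing_b)), collapse = ", "))
  num <- a$mean_hr[match(tasks, a$task)]
  den <- b$mean_hr[match(tasks, b$task)]
  ratios <- data.frame(task = tasks, ratio = num / den,
                       stringsAsFactors = FALSE)
  list(ratios = ratios, range = range(ratios$ratio))
}

#' Group-level PCI summaries
#'
#' For each group-task, PCI computed both ways: the mean (and SD) of
#' per-participant PCIs (primary, matching per-subject averaging) and the
#' ratio-of-group-means diagnostic
#' `(group mean working HR - group mean rest HR) / velocity`.  With a
#' common pre-set velocity the two coincide whenever every participant has
#' a rest measurement; on published group-mean tables they differ by a
#' percent or two through rounding and unequal completer sets, which is
#' why both are reported.
#'
#' @param summaries An [summarize_activities()] data frame.
#' @return Data frame `group`, `task`, `velocity`, `pci_mean`, `pci_sd`,
#'   `pci_of_means`, `n`.
#' @export
pci_table <- function(summaries) {
  walk <- summaries[summaries$velocity > 0, ]
  rest <- summaries[summaries$task == "rest", ]
  rest_mean <- tapply(rest$mean_hr, rest$group, mean)
  key <- interaction(walk$group, walk$task, drop = TRUE)
  rows <- lapply(split(walk, key), function(d) {
    data.frame(group = d$group[1], task = d$task[1], velocity = d$velocity[1],
               pci_mean = mean(d$pci), pci_sd = sd(d$pci),
               pci_of_means = pci(mean(d$mean_hr),
                                  rest_mean[[d$group[1]]], d$velocity[1]),
               n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$velocity, out$task), ]
  rownames(out) <- NULL
  out
}
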