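test_that("cohort generation matches group sizes and is seed-deterministic", {
  cohort <- generate_cohort(seed = 1)
  expect_equal(nrow(cohort), 28)
  expect_equal(as.vector(table(cohort$group)[c("unilateral", "bilateral", "control")]),
               c(9, 10, 9))
  expect_identical(cohort, generate_cohort(seed = 1))
  expect_false(identical(cohort$rmr, generate_cohort(seed = 2)$rmr))
})

test_that("degenerate zero-SD group yields profiles equal to the spec means", {
  spec <- group_spec("control", 5, 1800, 0, 60, 0, 75, 0)
  cohort <- generate_cohort(list(spec), seed = 3, economy_sdlog = 0)
  expect_equal(cohort$rmr, rep(1800, 5))
  expect_equal(cohort$rest_hr, rep(60, 5))
  expect_equal(cohort$economy_factor, rep(1, 5))
})

test_that("invalid group specifications are rejected", {
  expect_error(group_spec("control", 0, 1800, 100, 60, 5, 75, 7), "positive integer")
  expect_error(group_spec("control", 5, 1800, -1, 60, 5, 75, 7), "rmr_sd")
  expect_error(group_spec("control", 5, -10, 100, 60, 5, 75, 7), "rmr_mean")
  expect_error(group_spec("control", 5, 1800, 100, 150, 5, 75, 7), "rest_hr_mean")
})

test_that("economy factor is mean-one on average", {
  cohort <- generate_cohort(
    list(group_spec("control", 2000, 1800, 0, 60, 0, 75, 0)),
    seed = 4, economy_sdlog = 0.15)
  expect_lt(abs(mean(cohort$economy_factor) - 1),
            3 * sd(cohort$economy_factor) / sqrt(2000))
})

test_that("dropout honours completion probabilities", {
  cohort <- generate_cohort(seed = 1)
  tasks <- default_task_battery()

  sure <- lapply(tasks, function(tk) { tk$completion_prob <- numeric(0); tk })
  expect_true(all(apply_dropout(cohort, sure, seed = 1)$completed))

  # bilateral group at the fastest speed completes with probability 2/10:
  # across many seeds the mean number of completers converges to 2
  bil <- cohort[cohort$group == "bilateral", ]
  counts <- vapply(1:300, function(s) {
    d <- apply_dropout(bil, tasks, seed = s)
    sum(d$completed[d$task == "walk_1.34"])
  }, numeric(1))
  expect_lt(abs(mean(counts) - 2), 3 * sd(counts) / sqrt(300))
})

test_that("monotone dropout never recovers at a faster speed", {
  cohort <- generate_cohort(seed = 2)
  tasks <- default_task_battery()
  d <- apply_dropout(cohort, tasks, seed = 7, monotone = TRUE)
  speeds <- c("walk_0.48", "walk_0.67", "walk_0.89", "walk_1.12", "walk_1.34")
  for (id in unique(d$id)) {
    done <- d$completed[match(paste(id, speeds), paste(d$id, d$task))]
    expect_true(all(diff(done) <= 0))
  }
})

test_that("noiseless activity round-trips energy through the gas stream", {
  cfg <- noiseless_config(seed = 1)
  p <- list(id = "X1", group = "control", rmr = 1846, rest_hr = 54,
            body_mass = 80, economy_factor = 1)
  tgt <- subset(cfg$targets, group == "control" & task == "walk_0.89")
  tgt$hr_rest <- 54
  st <- simulate_activity(p, cfg$tasks$walk_0.89, cfg$models$control, tgt,
                          cfg$noise, seed = 1)
  gm <- steady_state_mean(st$gas, 5)
  em <- steady_state_mean(st$epochs, 5)
  tee <- weir_ee(gm$vo2_l_min, gm$vco2_l_min)
  tm <- cfg$models$control
  want <- tm$intercept + tm$beta_pac * em$pac_counts_min +
    tm$beta_hr * em$hr_bpm + rmr_per_min(1846)
  expect_equal(tee, want, tolerance = 1e-12)
  expect_equal(em$pac_counts_min, tgt$pac_mean)
  expect_equal(compute_rer(gm$vo2_l_min, gm$vco2_l_min), tgt$rer_mean)
})

test_that("rest task has zero counts and heart rate near resting", {
  cfg <- default_config(seed = 3)
  p <- list(id = "X2", group = "unilateral", rmr = 1776, rest_hr = 66,
            body_mass = 81, economy_factor = 1.05)
  tgt <- subset(cfg$targets, group == "unilateral" & task == "rest")
  tgt$hr_rest <- 66
  st <- simulate_activity(p, cfg$tasks$rest, cfg$models$unilateral, tgt,
                          cfg$noise, seed = 3)
  expect_true(all(st$epochs$pac_counts_min == 0))
  expect_lt(abs(mean(st$epochs$hr_bpm) - 66), 3 * cfg$noise$hr_sd + 5)
  gm <- steady_state_mean(st$gas, 5)
  expect_equal(weir_ee(gm$vo2_l_min, gm$vco2_l_min), rmr_per_min(1776),
               tolerance = 1e-12)
})

test_that("dropped-out participant-task yields empty streams, not an error", {
  cfg <- default_config(seed = 1)
  p <- list(id = "X3", group = "bilateral", rmr = 1596, rest_hr = 67,
            body_mass = 82, economy_factor = 1)
  tgt <- subset(cfg$targets, group == "bilateral" & task == "walk_1.34")
  tgt$hr_rest <- 67
  st <- simulate_activity(p, cfg$tasks$walk_1.34, cfg$models$bilateral, tgt,
                          cfg$noise, seed = 1, completed = FALSE)
  expect_equal(nrow(st$epochs), 0)
  expect_equal(nrow(st$gas), 0)
})

test_that("simulated steady-state PAC converges on the configured target", {
  cfg <- default_config(seed = 11)
  tgt <- subset(cfg$targets, group == "unilateral" & task == "walk_0.48")
  tgt$hr_rest <- 66
  econ_sd <- cfg$noise$economy_sdlog
  pac <- withr::with_seed(99, vapply(seq_len(200), function(i) {
    p <- list(id = paste0("S", i), group = "unilateral", rmr = 1776,
              rest_hr = 66, body_mass = 81,
              economy_factor = exp(rnorm(1, -econ_sd^2 / 2, econ_sd)))
    st <- simulate_activity(p, cfg$tasks$walk_0.48, cfg$models$unilateral,
                            tgt, cfg$noise, seed = i)
    steady_state_mean(st$epochs, 5)$pac_counts_min
  }, numeric(1)))
  expect_lt(abs(mean(pac) - 2643), 2 * sd(pac) / sqrt(200))
})

test_that("datasets round-trip through delimited files", {
  cfg <- run_config(seed = 5, groups = list(
    group_spec("control", 3, 1846, 191, 54, 4, 80, 7)))
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$participants$rmr, ds$participants$rmr, tolerance = 1e-12)
  expect_equal(back$epochs$pac_counts_min, ds$epochs$pac_counts_min,
               tolerance = 1e-12)
  expect_equal(back$gas$vo2_l_min, ds$gas$vo2_l_min, tolerance = 1e-12)
  expect_identical(back$completion$completed, ds$completion$completed)
  expect_equal(back$config$seed, 5)

  # empty streams produce header-only files
  empty <- ds
  empty$epochs <- ds$epochs[0, ]
  write_dataset(empty, dir)
  expect_equal(length(readLines(file.path(dir, "epochs.tsv"))), 1)
})

test_that("the default dataset covers the full reference cohort", {
  ds <- simulate_dataset(default_config(seed = 1))
  expect_equal(nrow(ds$participants), 28)
  expect_equal(sort(unique(ds$epochs$task)), sort(reference_tasks()$task))
  # every completed participant-task has a full 5-min stream at 30-s epochs
  n_per <- table(paste(ds$epochs$id, ds$epochs$task))
  expect_true(all(n_per == 10))
})
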