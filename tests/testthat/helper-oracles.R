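# Brute-force normal-equations OLS, independent of fit_paee_model():
# beta = (X'X)^{-1} X'y with an explicit solve.
ols_oracle <- function(X, y) {
  Xa <- cbind(intercept = 1, X)
  drop(solve(t(Xa) %*% Xa, t(Xa) %*% y))
}

# records lying on (or scattered around) a generating model
toy_records <- function(n_participants = 3, tasks_per = 4,
                        tm = default_true_models()$unilateral,
                        noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    rows <- expand.grid(
      participant = paste0("P", seq_len(n_participants)),
      task = paste0("t", seq_len(tasks_per)),
      stringsAsFactors = FALSE)
    rows$group <- "unilateral"
    rows$pac <- stats::runif(nrow(rows), 500, 5000)
    rows$hr <- stats::runif(nrow(rows), 70, 140)
    rows$criterion_paee <- tm$intercept + tm$beta_pac * rows$pac +
      tm$beta_hr * rows$hr + stats::rnorm(nrow(rows), 0, noise_sd)
    rows
  })
}

# small single-group configuration for fast end-to-end runs
small_config <- function(seed = 1, group = "unilateral", noiseless = FALSE) {
  base <- if (noiseless) noiseless_config(seed) else default_config(seed)
  run_config(seed = seed, groups = base$groups[group],
             tasks = base$tasks, models = base$models,
             noise = base$noise)
}
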