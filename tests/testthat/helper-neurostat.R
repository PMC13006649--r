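# Shared fixtures, built in code. Heavier objects (a small trained
# recognizer) are created lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# A modest recognizer trained on the full generator mixture. Much smaller
# than the production architecture, but accurate enough (MAE well under
# 2 %DO) to drive the controller in closed-loop tests.
quick_model <- function() {
  if (is.null(.fixtures$quick_model)) {
    ds <- generate_dataset(4000, do_gen_params(), seed = 2024)
    m <- build_model(mlp_config(hidden_sizes = c(128L, 64L)), seed = 7)
    m <- train_baseline_model(
      m, ds, training_config(epochs = 60, batch_size = 128, seed = 7,
                             input_jitter = 0.3, level_shift = 5))
    .fixtures$quick_model <- m
  }
  .fixtures$quick_model
}

# A model trained only on noise-free flat baselines (still with spikes), for
# the parameter-recovery property on constant windows.
flat_model <- function() {
  if (is.null(.fixtures$flat_model)) {
    p <- do_gen_params(trend_weights = c(stable = 1, increasing = 0,
                                         decreasing = 0),
                       drift_max = 0, noise_sd_range = c(0, 0))
    ds <- generate_dataset(3000, p, seed = 99)
    m <- build_model(mlp_config(hidden_sizes = c(64L, 32L)), seed = 3)
    m <- train_baseline_model(
      m, ds, training_config(epochs = 30, batch_size = 128, seed = 3))
    .fixtures$flat_model <- m
  }
  .fixtures$flat_model
}

# Generator parameters that produce no spikes (gaps larger than the trace).
spikeless_params <- function(...) {
  do_gen_params(gap_range = c(1e5, 1e5 + 1), noise_sd_range = c(0, 0), ...)
}

# Feed a controller state with one sample per second over a span.
feed_seconds <- function(state, times_s, do_values) {
  do_values <- rep_len(do_values, length(times_s))
  for (i in seq_along(times_s)) {
    state <- ingest_sample(state, process_sample(times_s[i] / 3600,
                                                 do_values[i],
                                                 time_s = times_s[i]))
  }
  state
}

# A controller state warmed up past the 60-minute window with a given
# smoothed baseline, for decision-rule tests.
warmed_state <- function(baseline_smooth, last_do = baseline_smooth,
                         agitate = 400, air = 0.5) {
  st <- new_controller_state(agitate_rate = agitate, air_flow = air)
  st$minute_values <- rep(baseline_smooth, 60)
  st$baseline_smooth <- baseline_smooth
  st$raw_baseline <- baseline_smooth
  st$last_do <- last_do
  st$last_time <- 3600
  st
}

# Row-subset a dataset without relying on package internals.
subset_dataset_for_test <- function(ds, idx) {
  structure(list(x = ds$x[idx, , drop = FALSE], y = ds$y[idx],
                 trend = ds$trend[idx], seed = ds$seed, params = ds$params),
            class = "do_dataset")
}
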