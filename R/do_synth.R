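#' Generator parameters for synthetic DO traces
#'
#' Bundles every distribution parameter used by the synthetic dissolved-oxygen
#' (DO) signal generator. The generator emulates the dynamics seen under
#' DO-stat operation: a slowly varying baseline (the DO level the broth
#' returns to while substrate is available), sharp upward spikes when glucose
#' is depleted, gradual post-feeding recovery, and sensor noise. All values
#' are overridable so they are explicit modelling assumptions, not constants.
#'
#' @param baseline_range numeric(2); range (\% air saturation) from which the
#'   baseline level at the start of a trace is drawn.
#' @param slope_range numeric(2); magnitude range of linear baseline slopes
#'   (\%DO per minute) for increasing/decreasing trends.
#' @param drift_max maximum absolute deviation (\%DO) of the slow random-walk
#'   drift superimposed on a stable baseline. `0` gives a perfectly constant
#'   baseline.
#' @param spike_height_range numeric(2); DO spike heights above baseline (\%DO).
#' @param rise_width_range numeric(2); spike rise times (minutes).
#' @param decay_width_range numeric(2); spike decay time constants (minutes).
#' @param gap_range numeric(2); gaps between the end of one spike's rise and
#'   the onset of the next (minutes).
#' @param noise_sd_range numeric(2); per-trace Gaussian sensor noise standard
#'   deviation (\%DO) is drawn uniformly from this range.
#' @param trend_weights named numeric; mixture weights for the trend kinds
#'   `stable`, `increasing`, `decreasing`. Normalized internally.
#' @param trace_length length (minutes) of each simulated long trace from
#'   which training windows are cut.
#' @param windows_per_trace number of 60-point windows sampled per trace.
#'
#' @return an object of class `do_gen_params` (a validated list).
#' @export
do_gen_params <- function(baseline_range = c(10, 70),
                          slope_range = c(0.05, 0.5),
                          drift_max = 2,
                          spike_height_range = c(5, 45),
                          rise_width_range = c(1, 5),
                          decay_width_range = c(2, 15),
                          gap_range = c(3, 30),
                          noise_sd_range = c(0, 1),
                          trend_weights = c(stable = 1, increasing = 1,
                                            decreasing = 1) / 3,
                          trace_length = 240L,
                          windows_per_trace = 6L) {
  p <- list(baseline_range = as.numeric(baseline_range),
            slope_range = as.numeric(slope_range),
            drift_max = as.numeric(drift_max),
            spike_height_range = as.numeric(spike_height_range),
            rise_width_range = as.numeric(rise_width_range),
            decay_width_range = as.numeric(decay_width_range),
            gap_range = as.numeric(gap_range),
            noise_sd_range = as.numeric(noise_sd_range),
            trend_weights = trend_weights / sum(trend_weights),
            trace_length = as.integer(trace_length),
            windows_per_trace = as.integer(windows_per_trace))
  ranges <- c("baseline_range", "slope_range", "spike_height_range",
              "rise_width_range", "decay_width_range", "gap_range",
              "noise_sd_range")
  for (r in ranges) {
    v <- p[[r]]
    if (length(v) != 2L || any(!is.finite(v)) || v[1] > v[2])
      stop("'", r, "' must be a finite non-decreasing range of length 2",
           call. = FALSE)
  }
  if (p$drift_max < 0) stop("'drift_max' must be >= 0", call. = FALSE)
  if (p$rise_width_range[1] < 1 || p$decay_width_range[1] < 1)
    stop("spike widths must be >= 1 minute", call. = FALSE)
  if (p$noise_sd_range[1] < 0) stop("noise sd must be >= 0", call. = FALSE)
  if (!setequal(names(p$trend_weights),
                c("stable", "increasing", "decreasing")))
    stop("'trend_weights' must be named stable/increasing/decreasing",
         call. = FALSE)
  if (p$trace_length < 60L) stop("'trace_length' must be >= 60", call. = FALSE)
  if (p$windows_per_trace < 1L)
    stop("'windows_per_trace' must be >= 1", call. = FALSE)
  structure(p, class = "do_gen_params")
}

trend_kinds <- c("stable", "increasing", "decreasing")

#' Generate a DO baseline trajectory
#'
#' Draws a minute-resolution baseline, one of three trend kinds: `stable`
#' (constant level plus a bounded slow random walk), `increasing` or
#' `decreasing` (linear ramp). The slope of a ramp is capped so the
#' trajectory stays inside \[5, 95\] \%DO; values are additionally clipped to
#' the physical \[0, 100\] range. Uses the current R random number generator
#' state; seed with [set.seed()] for reproducibility.
#'
#' @param length_min trajectory length in minutes (>= 60).
#' @param trend_kind one of `"stable"`, `"increasing"`, `"decreasing"`.
#' @param params a [do_gen_params()] object.
#' @param level optional fixed starting level (\%DO); drawn from
#'   `params$baseline_range` when `NULL`.
#' @param slope optional fixed slope magnitude (\%DO/min) for ramps; drawn
#'   from `params$slope_range` when `NULL`.
#'
#' @return an object of class `do_baseline`: list with `values` (numeric of
#'   length `length_min`) and `trend_kind`.
#' @export
generate_baseline_trajectory <- function(length_min, trend_kind,
                                         params = do_gen_params(),
                                         level = NULL, slope = NULL) {
  length_min <- as.integer(length_min)
  if (is.na(length_min) || length_min < 60L)
    stop("'length_min' must be >= 60 minutes", call. = FALSE)
  if (!is.character(trend_kind) || length(trend_kind) != 1L ||
      !trend_kind %in% trend_kinds)
    stop("'trend_kind' must be one of ",
         paste(sQuote(trend_kinds), collapse = ", "), call. = FALSE)
  stopifnot(inherits(params, "do_gen_params"))
  if (is.null(level))
    level <- stats::runif(1, params$baseline_range[1], params$baseline_range[2])
  tt <- seq_len(length_min) - 1
  if (trend_kind == "stable") {
    if (params$drift_max > 0) {
      # random walk, rescaled so the max excursion never exceeds drift_max
      step_sd <- params$drift_max / (2 * sqrt(length_min))
      walk <- cumsum(c(0, stats::rnorm(length_min - 1L, 0, step_sd)))
      m <- max(abs(walk))
      if (m > params$drift_max) walk <- walk * params$drift_max / m
    } else {
      walk <- numeric(length_min)
    }
    values <- level + walk
  } else {
    if (is.null(slope))
      slope <- stats::runif(1, params$slope_range[1], params$slope_range[2])
    headroom <- if (trend_kind == "increasing") (95 - level) else (level - 5)
    slope <- min(slope, max(headroom, 0) / (length_min - 1))
    sgn <- if (trend_kind == "increasing") 1 else -1
    values <- level + sgn * slope * tt
  }
  values <- pmin(pmax(values, 0), 100)
  structure(list(values = values, trend_kind = trend_kind),
            class = "do_baseline")
}

#' Build a table of spike specifications
#'
#' @param onset_index spike onset positions (minutes, 1-based index into the
#'   trajectory).
#' @param height spike heights above baseline (\%DO, > 0).
#' @param rise_width rise times (minutes, >= 1).
#' @param decay_width decay time constants (minutes, >= 1).
#' @return a `data.frame` with one row per spike, sorted by onset.
#' @export
spike_spec <- function(onset_index, height, rise_width, decay_width) {
  s <- data.frame(onset_index = as.numeric(onset_index),
                  height = as.numeric(height),
                  rise_width = as.numeric(rise_width),
                  decay_width = as.numeric(decay_width))
  if (nrow(s) > 0) {
    if (any(s$height <= 0)) stop("spike heights must be > 0", call. = FALSE)
    if (any(s$rise_width < 1) || any(s$decay_width < 1))
      stop("spike widths must be >= 1 minute", call. = FALSE)
    s <- s[order(s$onset_index), , drop = FALSE]
  }
  s
}

# Spike shape: linear rise from onset to apex over rise_width, then an
# exponential-like decay that returns to the baseline exactly decay_width
# minutes after the apex (a shifted exponential rescaled to hit zero, so a
# spike's support is finite and the signal genuinely revisits the baseline
# between spikes -- the defining feature of DO-stat traces).
spike_contribution <- function(tt, onset, height, rise, decay) {
  out <- numeric(length(tt))
  apex <- onset + rise
  up <- tt >= onset & tt <= apex
  out[up] <- height * (tt[up] - onset) / rise
  dn <- tt > apex & tt <= apex + decay
  u <- (tt[dn] - apex) / decay           # decay progress in [0, 1]
  k <- 4                                  # curvature of the recovery
  out[dn] <- height * (exp(-k * u) - exp(-k)) / (1 - exp(-k))
  out
}

#' Superimpose DO spikes and sensor noise on a baseline
#'
#' Adds glucose-depletion DO spikes and Gaussian sensor noise to a baseline
#' trajectory, then clips to the physical \[0, 100\] \%DO range. A spike
#' rises linearly to `height` over `rise_width` minutes and decays back to
#' the baseline over the following `decay_width` minutes along an
#' exponential-like recovery, reaching the baseline exactly at the end of
#' the decay (post-feeding DO returns to the substrate-present level).
#'
#' @param baseline a `do_baseline` object (or bare numeric vector of \%DO).
#' @param spikes a [spike_spec()] data frame (possibly empty).
#' @param noise_sd Gaussian noise standard deviation (\%DO, >= 0).
#' @return numeric vector of simulated DO readings, same length as the
#'   baseline.
#' @export
superimpose_spikes <- function(baseline, spikes = spike_spec(numeric(0),
                                                             numeric(0),
                                                             numeric(0),
                                                             numeric(0)),
                               noise_sd = 0) {
  values <- if (inherits(baseline, "do_baseline")) baseline$values
            else as.numeric(baseline)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || !is.finite(noise_sd) ||
      noise_sd < 0)
    stop("'noise_sd' must be a single non-negative number", call. = FALSE)
  tt <- seq_along(values)
  y <- values
  if (nrow(spikes) > 0) {
    if (any(spikes$onset_index < 1 | spikes$onset_index > length(values)))
      stop("spike onsets must lie within the trajectory", call. = FALSE)
    if (is.unsorted(spikes$onset_index))
      stop("spike onsets must be sorted", call. = FALSE)
    for (k in seq_len(nrow(spikes)))
      y <- y + spike_contribution(tt, spikes$onset_index[k], spikes$height[k],
                                  spikes$rise_width[k], spikes$decay_width[k])
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  pmin(pmax(y, 0), 100)
}

# Draw a random spike schedule spanning a trace of given length.
random_spikes <- function(length_min, params) {
  onsets <- heights <- rises <- decays <- numeric(0)
  pos <- stats::runif(1, params$gap_range[1], params$gap_range[2])
  while (pos <= length_min) {
    rise <- stats::runif(1, params$rise_width_range[1],
                         params$rise_width_range[2])
    onsets <- c(onsets, pos)
    heights <- c(heights, stats::runif(1, params$spike_height_range[1],
                                       params$spike_height_range[2]))
    rises <- c(rises, rise)
    decays <- c(decays, stats::runif(1, params$decay_width_range[1],
                                     params$decay_width_range[2]))
    pos <- pos + rise + stats::runif(1, params$gap_range[1],
                                     params$gap_range[2])
  }
  spike_spec(onsets, heights, rises, decays)
}

# Derived per-trace seed; kept below 2^31 - 1.
derive_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 16807) %% 2147483647
}

#' Generate a labeled synthetic dataset of DO windows
#'
#' Simulates long DO traces (baseline + spikes + noise), cuts 60-minute
#' windows from them, and labels each window with the ground-truth baseline
#' value at the window's final time point. This is the training corpus for
#' the baseline-recognition network: baselines cannot be measured by a
#' physical sensor, so supervised examples must be synthesized.
#'
#' @param n number of windows to generate (default 15000).
#' @param params a [do_gen_params()] object.
#' @param seed integer master seed. Per-trace seeds are derived from it with
#'   a counter scheme, so datasets are reproducible.
#' @return an object of class `do_dataset`: list with `x` (n x 60 numeric
#'   matrix of DO readings), `y` (numeric labels, \%DO), `trend`
#'   (character), the construction records `noise_sd` (per-window sensor
#'   noise sd) and `spike_at_end` (noise-free spike contribution at the
#'   label's time point, \%DO), `seed`, and `params`.
#' @export
generate_dataset <- function(n = 15000L, params = do_gen_params(), seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1", call. = FALSE)
  stopifnot(inherits(params, "do_gen_params"))
  wlen <- 60L
  wpt <- min(params$windows_per_trace, params$trace_length - wlen + 1L)
  n_traces <- ceiling(n / wpt)
  x <- matrix(NA_real_, n, wlen)
  y <- numeric(n)
  trend <- character(n)
  noise_sd_w <- numeric(n)
  spike_at_end <- numeric(n)
  filled <- 0L
  for (i in seq_len(n_traces)) {
    set.seed(derive_seed(seed, i))
    kind <- sample(trend_kinds, 1L,
                   prob = params$trend_weights[trend_kinds])
    base <- generate_baseline_trajectory(params$trace_length, kind, params)
    spikes <- random_spikes(params$trace_length, params)
    noise_sd <- stats::runif(1, params$noise_sd_range[1],
                             params$noise_sd_range[2])
    trace <- superimpose_spikes(base, spikes, noise_sd)
    spike_sum <- superimpose_spikes(
      structure(list(values = numeric(params$trace_length),
                     trend_kind = kind), class = "do_baseline"),
      spikes, noise_sd = 0)
    starts <- sample.int(params$trace_length - wlen + 1L, wpt,
                         replace = FALSE)
    for (s in starts) {
      if (filled >= n) break
      filled <- filled + 1L
      x[filled, ] <- trace[s:(s + wlen - 1L)]
      y[filled] <- base$values[s + wlen - 1L]
      trend[filled] <- kind
      noise_sd_w[filled] <- noise_sd
      spike_at_end[filled] <- spike_sum[s + wlen - 1L]
    }
    if (filled >= n) break
  }
  structure(list(x = x, y = y, trend = trend,
                 noise_sd = noise_sd_w, spike_at_end = spike_at_end,
                 seed = as.integer(seed), params = params),
            class = "do_dataset")
}

#' @export
print.do_dataset <- function(x, ...) {
  cat("<do_dataset> ", nrow(x$x), " windows x ", ncol(x$x),
      " points; labels ", sprintf("%.1f-%.1f", min(x$y), max(x$y)),
      " %DO; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  structure(list(x = ds$x[idx, , drop = FALSE], y = ds$y[idx],
                 trend = ds$trend[idx],
                 noise_sd = ds$noise_sd[idx],
                 spike_at_end = ds$spike_at_end[idx],
                 seed = ds$seed, params = ds$params),
            class = "do_dataset")
}

#' Split a dataset into training and test halves
#'
#' Shuffles window indices with the given seed and assigns the first
#' `floor(n * ratio)` to the training set, the remainder to the test set
#' (so with an odd count the training set is the smaller half).
#'
#' @param ds a `do_dataset`.
#' @param ratio training fraction, strictly between 0 and 1 (default 0.5,
#'   the 1:1 protocol).
#' @param seed integer shuffle seed.
#' @return list with elements `train` and `test`, both `do_dataset`s forming
#'   a disjoint, exhaustive partition of `ds`.
#' @export
split_dataset <- function(ds, ratio = 0.5, seed = 1L) {
  stopifnot(inherits(ds, "do_dataset"))
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1)
    stop("'ratio' must lie strictly between 0 and 1", call. = FALSE)
  n <- nrow(ds$x)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  n_train <- floor(n * ratio)
  if (n_train < 1L || n_train >= n)
    stop("'ratio' leaves an empty partition for n = ", n, call. = FALSE)
  list(train = subset_dataset(ds, perm[seq_len(n_train)]),
       test = subset_dataset(ds, perm[(n_train + 1L):n]))
}

#' Write / read a dataset as CSV with a JSON sidecar
#'
#' The CSV holds columns `do_00` ... `do_59`, `baseline_label`, and `trend`;
#' the sidecar `<path>.params.json` records the generator parameters and
#' master seed so a written dataset is self-describing.
#'
#' @param ds a `do_dataset`.
#' @param path output CSV path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns a
#'   `do_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "do_dataset"))
  df <- as.data.frame(ds$x)
  names(df) <- sprintf("do_%02d", seq_len(ncol(ds$x)) - 1L)
  df$baseline_label <- ds$y
  df$trend <- ds$trend
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(seed = ds$seed, generator_params = unclass(ds$params))
  # keep the mixture weights a named JSON object, not a bare array
  side$generator_params$trend_weights <-
    as.list(side$generator_params$trend_weights)
  jsonlite::write_json(side, paste0(path, ".params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  do_cols <- grep("^do_[0-9]+$", names(df), value = TRUE)
  if (length(do_cols) == 0L || !"baseline_label" %in% names(df))
    stop("not a dataset CSV: expected do_NN columns and 'baseline_label'",
         call. = FALSE)
  sidecar <- paste0(path, ".params.json")
  seed <- NA_integer_
  params <- do_gen_params()
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    seed <- as.integer(side$seed)
    gp <- side$generator_params
    gp$trend_weights <- unlist(gp$trend_weights)
    params <- do.call(do_gen_params, gp)
  }
  structure(list(x = as.matrix(df[do_cols]),
                 y = df$baseline_label,
                 trend = if ("trend" %in% names(df)) df$trend
                         else rep(NA_character_, nrow(df)),
                 seed = seed, params = params),
            class = "do_dataset")
}
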