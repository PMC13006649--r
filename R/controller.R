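#' Controller parameter set
#'
#' The named setpoints of the DO-stat control logic. The defaults are the
#' growth-phase configuration used for autonomous runs: `baseline_lb` 25,
#' `baseline_ub` 50, `baseline_increase` 15, `threshold_increase` 40 (\%DO)
#' and `v_glc` 21 g/L/h, with oxygen-supply steps of 20 rpm / 0.05 L/min,
#' actuator limits of 400-800 rpm and 0.5-1.5 L/min, nitrogen feed at
#' 1.0 g/L/h, induction at 10 h with 0.3 mmol/L IPTG, and a 3-minute forced
#' stop on every glucose pulse.
#'
#' @param baseline_lb lower bound on the smoothed baseline (\%DO); below it
#'   the broth is judged oxygen-deficient and oxygen supply is stepped up.
#' @param baseline_ub upper bound on the smoothed baseline (\%DO); above it
#'   oxygen supply is stepped down.
#' @param baseline_increase offset above the smoothed baseline at which a
#'   running glucose pulse stops (\%DO).
#' @param threshold_increase offset above the smoothed baseline at which a
#'   glucose pulse starts (\%DO); must exceed `baseline_increase`.
#' @param v_glc glucose feed rate during a pulse (g per L of culture per h);
#'   0 disables glucose addition entirely.
#' @param v_ns nitrogen (yeast extract) feed rate once latched (g/L/h).
#' @param induction_time run time after which induction fires (h).
#' @param iptg_dose IPTG dose added at induction (mmol/L).
#' @param agitate_step,air_step oxygen-supply adjustment steps (rpm, L/min).
#' @param agitate_min,agitate_max agitation bounds (rpm).
#' @param air_min,air_max airflow bounds (L/min).
#' @param max_pulse_duration forced-stop limit for one glucose pulse (min).
#' @return an object of class `controller_params`.
#' @export
controller_params <- function(baseline_lb = 25, baseline_ub = 50,
                              baseline_increase = 15, threshold_increase = 40,
                              v_glc = 21, v_ns = 1.0,
                              induction_time = 10, iptg_dose = 0.3,
                              agitate_step = 20, air_step = 0.05,
                              agitate_min = 400, agitate_max = 800,
                              air_min = 0.5, air_max = 1.5,
                              max_pulse_duration = 3) {
  p <- list(baseline_lb = baseline_lb, baseline_ub = baseline_ub,
            baseline_increase = baseline_increase,
            threshold_increase = threshold_increase,
            v_glc = v_glc, v_ns = v_ns,
            induction_time = induction_time, iptg_dose = iptg_dose,
            agitate_step = agitate_step, air_step = air_step,
            agitate_min = agitate_min, agitate_max = agitate_max,
            air_min = air_min, air_max = air_max,
            max_pulse_duration = max_pulse_duration)
  if (any(!vapply(p, is.numeric, logical(1))))
    stop("all controller parameters must be numeric", call. = FALSE)
  if (p$baseline_lb >= p$baseline_ub)
    stop("'baseline_lb' must be < 'baseline_ub'", call. = FALSE)
  if (p$baseline_increase < 0 ||
      p$threshold_increase <= p$baseline_increase)
    stop("'threshold_increase' must be > 'baseline_increase' >= 0",
         call. = FALSE)
  if (p$v_glc < 0) stop("'v_glc' must be >= 0", call. = FALSE)
  if (p$v_ns < 0) stop("'v_ns' must be >= 0", call. = FALSE)
  if (p$max_pulse_duration <= 0)
    stop("'max_pulse_duration' must be > 0", call. = FALSE)
  if (p$agitate_min > p$agitate_max || p$air_min > p$air_max)
    stop("actuator bounds must satisfy min <= max", call. = FALSE)
  structure(p, class = "controller_params")
}

#' Phase-specific parameter sets
#'
#' The controller loads different parameters for the growth and induction
#' phases. The induction set is the growth set with `baseline_increase`,
#' `threshold_increase` and `v_glc` overridden; the defaults (5, 10 \%DO and
#' 7 g/L/h) tighten feeding during expression, when excess substrate drives
#' overflow metabolism.
#'
#' @param growth a [controller_params()] for the growth phase.
#' @param induction_overrides named list of values overriding the growth set
#'   during induction (typically `baseline_increase`, `threshold_increase`,
#'   `v_glc`).
#' @return an object of class `phase_param_set` with elements `growth` and
#'   `induction`.
#' @export
phase_param_set <- function(growth = controller_params(),
                            induction_overrides = list(
                              baseline_increase = 5,
                              threshold_increase = 10,
                              v_glc = 7)) {
  stopifnot(inherits(growth, "controller_params"))
  unknown <- setdiff(names(induction_overrides), names(growth))
  if (length(unknown) > 0)
    stop("unknown induction override(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  induction <- do.call(controller_params,
                       utils::modifyList(unclass(growth),
                                         induction_overrides))
  structure(list(growth = growth, induction = induction),
            class = "phase_param_set")
}

#' Construct a process sample
#'
#' @param runtime_h elapsed fermentation time (h).
#' @param do_realtime DO sensor reading (\% air saturation, in \[0, 100\]).
#' @param time_s timestamp (s).
#' @return a `process_sample` list.
#' @export
process_sample <- function(runtime_h, do_realtime, time_s = runtime_h * 3600) {
  if (!is.finite(do_realtime) || do_realtime < 0 || do_realtime > 100)
    stop("'do_realtime' must lie in [0, 100]", call. = FALSE)
  structure(list(runtime_h = runtime_h, do_realtime = do_realtime,
                 time_s = time_s),
            class = "process_sample")
}

#' Fresh controller state
#'
#' @param smoother an [sg_smoother()] for the baseline stream.
#' @param agitate_rate,air_flow initial actuator settings (rpm, L/min).
#' @param window_length sliding-window length in minutes (the recognition
#'   model's input size).
#' @return an object of class `controller_state`. Key fields: `phase`
#'   (growth/induction), `minute_values` (the DO window, minute means),
#'   `raw_baseline` / `baseline_smooth` (\%DO, `NA` during warm-up),
#'   `feeding_active`, `nitrogen_started`, `induced` (latches), actuator
#'   fields, and `events` (decision log).
#' @export
new_controller_state <- function(smoother = sg_smoother(),
                                 agitate_rate = 400, air_flow = 0.5,
                                 window_length = 60L) {
  structure(list(phase = "growth",
                 window_length = as.integer(window_length),
                 minute_values = numeric(0),
                 second_buffer = numeric(120), second_count = 0L,
                 current_minute = NA_integer_, last_time = -Inf,
                 new_minute = FALSE,
                 aggregate = "mean",
                 last_do = NA_real_, runtime_h = 0,
                 raw_baseline = NA_real_, baseline_smooth = NA_real_,
                 smoother = smoother,
                 feeding_active = FALSE, feed_elapsed_s = 0,
                 glc_ever_triggered = FALSE,
                 nitrogen_started = FALSE, induced = FALSE,
                 agitate_rate = agitate_rate, air_flow = air_flow,
                 glc_pump_on = FALSE, ns_pump_on = FALSE,
                 glc_feed_rate = 0, ns_feed_rate = 0,
                 temperature = 37, iptg_dose = 0,
                 events = vector("list", 64L), n_events = 0L),
            class = "controller_state")
}

log_event <- function(state, time_s, event, detail = NA_real_) {
  n <- state$n_events + 1L
  if (n > length(state$events))
    state$events <- c(state$events, vector("list", length(state$events)))
  state$events[[n]] <- list(time_s = time_s, event = event, detail = detail)
  state$n_events <- n
  state
}

#' Extract the event log as a data frame
#'
#' @param state a `controller_state` (or a closed-loop run result).
#' @return `data.frame` with columns `time_s`, `event`, `detail`.
#' @export
event_log <- function(state) {
  if (inherits(state, "neurostat_run")) state <- state$controller
  ev <- state$events[seq_len(state$n_events)]
  data.frame(time_s = vapply(ev, `[[`, numeric(1), "time_s"),
             event = vapply(ev, `[[`, character(1), "event"),
             detail = vapply(ev, `[[`, numeric(1), "detail"))
}

#' Current actuator command
#'
#' @param state a `controller_state`.
#' @return list with `agitate_rate`, `air_flow`, `glucose_pump_on`,
#'   `nitrogen_pump_on`, `glc_feed_rate`, `ns_feed_rate`,
#'   `temperature_setpoint`, `iptg_dose_mmol_per_l`.
#' @export
actuator_command <- function(state) {
  list(agitate_rate = state$agitate_rate, air_flow = state$air_flow,
       glucose_pump_on = state$glc_pump_on,
       nitrogen_pump_on = state$ns_pump_on,
       glc_feed_rate = state$glc_feed_rate,
       ns_feed_rate = state$ns_feed_rate,
       temperature_setpoint = state$temperature,
       iptg_dose_mmol_per_l = state$iptg_dose)
}

# Lean internal ingest used by the closed-loop driver.
ingest_core <- function(state, time_s, do_value, runtime_h) {
  minute <- time_s %/% 60
  state$new_minute <- FALSE
  if (is.na(state$current_minute)) {
    state$current_minute <- minute
  } else if (minute != state$current_minute) {
    if (state$second_count > 0L) {
      vals <- state$second_buffer[seq_len(state$second_count)]
      agg <- if (state$aggregate == "mean") mean(vals)
             else vals[length(vals)]
      mv <- c(state$minute_values, agg)
      if (length(mv) > state$window_length)
        mv <- mv[(length(mv) - state$window_length + 1L):length(mv)]
      state$minute_values <- mv
      state$new_minute <- TRUE
    }
    state$current_minute <- minute
    state$second_count <- 0L
  }
  state$second_count <- state$second_count + 1L
  state$second_buffer[state$second_count] <- do_value
  state$last_do <- do_value
  state$last_time <- time_s
  state$runtime_h <- runtime_h
  state
}

#' Ingest one per-second DO sample
#'
#' Samples are buffered within the current minute; on a minute rollover the
#' aggregate of the completed minute (arithmetic mean by default) is
#' appended to the sliding window, which is trimmed to the most recent
#' `window_length` minutes. Out-of-order samples are rejected.
#'
#' @param state a `controller_state`.
#' @param sample a [process_sample()].
#' @return the updated `controller_state`; `state$new_minute` is `TRUE` when
#'   a minute aggregate was just appended.
#' @export
ingest_sample <- function(state, sample) {
  stopifnot(inherits(state, "controller_state"))
  if (sample$time_s <= state$last_time)
    stop("out-of-order sample: t = ", sample$time_s, " s after t = ",
         state$last_time, " s", call. = FALSE)
  if (!is.finite(sample$do_realtime) || sample$do_realtime < 0 ||
      sample$do_realtime > 100)
    stop("'do_realtime' must lie in [0, 100]", call. = FALSE)
  ingest_core(state, sample$time_s, sample$do_realtime, sample$runtime_h)
}

# Recognizer dispatch: a trained model or a plain function(window) -> %DO.
recognize_baseline <- function(model, window) {
  if (inherits(model, "baseline_mlp")) predict_baseline(model, window)
  else if (is.function(model)) model(window)
  else stop("'model' must be a baseline_mlp or a function", call. = FALSE)
}

#' Update the recognized baseline after a minute rollover
#'
#' When the sliding window holds a full `window_length` minutes, the window
#' is passed to the recognition model and the raw estimate through the
#' causal Savitzky-Golay smoother. During warm-up (shorter window) the
#' update is skipped and `baseline_smooth` stays `NA`, so no
#' baseline-dependent decision can fire.
#'
#' @param state a `controller_state` (with `new_minute = TRUE`).
#' @param model a trained `baseline_mlp`, or a function `(window) -> \%DO`
#'   standing in for one (useful for testing alternative recognizers).
#' @return the updated `controller_state`.
#' @export
update_baseline <- function(state, model) {
  stopifnot(inherits(state, "controller_state"))
  if (length(state$minute_values) < state$window_length)
    return(state)
  raw <- recognize_baseline(model, state$minute_values)
  state$raw_baseline <- raw
  upd <- smooth_update(state$smoother, raw)
  state$smoother <- upd$state
  state$baseline_smooth <- upd$value
  log_event(state, state$last_time, "baseline_update", upd$value)
}

#' Oxygen-supply decision (once per minute)
#'
#' If the smoothed baseline is below `baseline_lb` the broth is judged
#' oxygen-deficient: agitation is increased by `agitate_step` and airflow by
#' `air_step`, clamped to their maxima. Above `baseline_ub` both are
#' decreased by one step, clamped to their minima. Inside the dead band
#' nothing changes. Comparisons are strict, as specified for the control
#' rules; ties produce no action.
#'
#' @param state a `controller_state` with an available `baseline_smooth`.
#' @param params the active [controller_params()].
#' @return the updated `controller_state`.
#' @export
decide_oxygen <- function(state, params) {
  stopifnot(inherits(state, "controller_state"),
            inherits(params, "controller_params"))
  bs <- state$baseline_smooth
  if (is.na(bs)) return(state)
  if (bs < params$baseline_lb) {
    agitate <- min(state$agitate_rate + params$agitate_step,
                   params$agitate_max)
    air <- min(state$air_flow + params$air_step, params$air_max)
    if (agitate != state$agitate_rate || air != state$air_flow) {
      state$agitate_rate <- agitate
      state$air_flow <- air
      state <- log_event(state, state$last_time, "oxygen_up", agitate)
    }
  } else if (bs > params$baseline_ub) {
    agitate <- max(state$agitate_rate - params$agitate_step,
                   params$agitate_min)
    air <- max(state$air_flow - params$air_step, params$air_min)
    if (agitate != state$agitate_rate || air != state$air_flow) {
      state$agitate_rate <- agitate
      state$air_flow <- air
      state <- log_event(state, state$last_time, "oxygen_down", agitate)
    }
  }
  state
}

#' Glucose feeding decision (every second)
#'
#' A pulse starts when `DO_realtime` rises strictly above
#' `baseline_smooth + threshold_increase` (glucose judged depleted) and
#' stops when it falls strictly below `baseline_smooth + baseline_increase`.
#' A safety rule forcibly stops any pulse that has run for
#' `max_pulse_duration` minutes regardless of DO, guarding against
#' overfeeding under delayed DO response. No decision fires while
#' `baseline_smooth` is unavailable (warm-up).
#'
#' @param state a `controller_state` (after [ingest_sample()]).
#' @param params the active [controller_params()].
#' @param dt_s seconds elapsed since the previous feed decision (default 1).
#' @return the updated `controller_state`.
#' @export
decide_glucose_feed <- function(state, params, dt_s = 1) {
  stopifnot(inherits(state, "controller_state"),
            inherits(params, "controller_params"))
  bs <- state$baseline_smooth
  if (is.na(bs) || is.na(state$last_do)) return(state)
  if (!state$feeding_active) {
    if (state$last_do > bs + params$threshold_increase) {
      state$feeding_active <- TRUE
      state$glc_pump_on <- TRUE
      state$glc_feed_rate <- params$v_glc
      state$feed_elapsed_s <- 0
      state$glc_ever_triggered <- TRUE
      state <- log_event(state, state$last_time, "feed_start", params$v_glc)
    }
  } else {
    state$feed_elapsed_s <- state$feed_elapsed_s + dt_s
    if (state$last_do < bs + params$baseline_increase) {
      state$feeding_active <- FALSE
      state$glc_pump_on <- FALSE
      state <- log_event(state, state$last_time, "feed_stop",
                         state$feed_elapsed_s)
    } else if (state$feed_elapsed_s >= params$max_pulse_duration * 60) {
      state$feeding_active <- FALSE
      state$glc_pump_on <- FALSE
      state <- log_event(state, state$last_time, "feed_forced_stop",
                         state$feed_elapsed_s)
    }
  }
  state
}

#' Nitrogen feeding decision
#'
#' Constant-rate nitrogen (yeast extract) feeding starts with the first
#' glucose trigger and never stops thereafter (latch semantics).
#'
#' @param state a `controller_state`.
#' @param params the active [controller_params()].
#' @return the updated `controller_state`.
#' @export
decide_nitrogen_feed <- function(state, params) {
  stopifnot(inherits(state, "controller_state"),
            inherits(params, "controller_params"))
  if (!state$nitrogen_started && state$glc_ever_triggered) {
    state$nitrogen_started <- TRUE
    state$ns_pump_on <- TRUE
    state$ns_feed_rate <- params$v_ns
    state <- log_event(state, state$last_time, "nitrogen_start", params$v_ns)
  }
  state
}

#' Induction decision
#'
#' The first sample whose runtime strictly exceeds `induction_time` fires a
#' one-shot induction: the IPTG dose is commanded, the temperature setpoint
#' drops from 37 to 28 degrees C, the phase switches to induction, and the
#' induction parameter set becomes active. The latch never reverts.
#'
#' @param state a `controller_state`.
#' @param phase_params a [phase_param_set()].
#' @return the updated `controller_state`.
#' @export
decide_induction <- function(state, phase_params) {
  stopifnot(inherits(state, "controller_state"),
            inherits(phase_params, "phase_param_set"))
  if (!state$induced &&
      state$runtime_h > phase_params$growth$induction_time) {
    state$induced <- TRUE
    state$phase <- "induction"
    state$iptg_dose <- phase_params$growth$iptg_dose
    state$temperature <- 28
    state <- log_event(state, state$last_time, "induction",
                       phase_params$growth$iptg_dose)
  }
  state
}

#' Active parameter set for the current phase
#'
#' @param state a `controller_state`.
#' @param phase_params a [phase_param_set()].
#' @return the [controller_params()] in force.
#' @export
active_params <- function(state, phase_params) {
  if (state$phase == "induction") phase_params$induction
  else phase_params$growth
}

#' Run the full closed loop: plant, recognizer, smoother, controller
#'
#' Interleaves 1-second plant steps with the controller at its stated
#' cadences: feeding and induction decisions every second, baseline
#' recognition and the oxygen-supply decision once per minute (after the
#' minute aggregate is appended and once the 60-minute window is full). The
#' run is deterministic given `seed`.
#'
#' @param plant a [plant_params()].
#' @param model a trained `baseline_mlp` or a recognizer function
#'   `(window) -> \%DO`.
#' @param smoother an [sg_smoother()].
#' @param phase_params a [phase_param_set()].
#' @param duration_h simulated hours.
#' @param seed integer RNG seed (sensor noise).
#' @param record_every record one trajectory row every this many seconds.
#' @return an object of class `neurostat_run`: list with `trajectory` (a
#'   `data.frame`: `time_s`, `do_realtime`, `raw_baseline`,
#'   `baseline_smooth`, `agitate_rpm`, `air_lpm`, `glc_pump`, `ns_pump`,
#'   `temp_c`, `glucose_g_l`, `biomass`, `volume_l`), `events`
#'   (a `data.frame` decision log), `controller` and `plant` (final states),
#'   and `seed`.
#' @export
run_closed_loop <- function(plant = plant_params(), model,
                            smoother = sg_smoother(),
                            phase_params = phase_param_set(),
                            duration_h = 24, seed = 1L, record_every = 1L) {
  stopifnot(inherits(plant, "plant_params"),
            inherits(phase_params, "phase_param_set"))
  # force lazy arguments before seeding so their construction cannot
  # consume random numbers mid-run
  force(model); force(smoother)
  set.seed(as.integer(seed))
  ps <- init_plant_state(plant)
  cs <- new_controller_state(smoother = smoother,
                             agitate_rate = phase_params$growth$agitate_min,
                             air_flow = phase_params$growth$air_min)
  n <- as.integer(round(duration_h * 3600))
  record_every <- as.integer(record_every)
  n_rec <- n %/% record_every
  traj <- matrix(NA_real_, n_rec, 12)
  rec <- 0L
  for (t in seq_len(n)) {
    ps <- step_plant(ps, actuator_command(cs), plant, dt = 1)
    do_now <- sensor_reading(ps)
    cs <- ingest_core(cs, ps$time, do_now, ps$time / 3600)
    if (cs$new_minute && length(cs$minute_values) >= cs$window_length) {
      cs <- update_baseline(cs, model)
      cs <- decide_oxygen(cs, active_params(cs, phase_params))
    }
    cs <- decide_induction(cs, phase_params)
    ap <- active_params(cs, phase_params)
    cs <- decide_glucose_feed(cs, ap, dt_s = 1)
    cs <- decide_nitrogen_feed(cs, ap)
    if (t %% record_every == 0L) {
      rec <- rec + 1L
      traj[rec, ] <- c(ps$time, do_now, cs$raw_baseline, cs$baseline_smooth,
                       cs$agitate_rate, cs$air_flow,
                       as.numeric(cs$glc_pump_on), as.numeric(cs$ns_pump_on),
                       cs$temperature, ps$glucose, ps$biomass, ps$volume)
    }
  }
  traj <- as.data.frame(traj[seq_len(rec), , drop = FALSE])
  names(traj) <- c("time_s", "do_realtime", "raw_baseline", "baseline_smooth",
                   "agitate_rpm", "air_lpm", "glc_pump", "ns_pump", "temp_c",
                   "glucose_g_l", "biomass", "volume_l")
  structure(list(trajectory = traj, events = event_log(cs),
                 controller = cs, plant = ps, seed = as.integer(seed)),
            class = "neurostat_run")
}

#' @export
print.neurostat_run <- function(x, ...) {
  tr <- x$trajectory
  cat("<neurostat_run> ", nrow(tr), " recorded steps (",
      sprintf("%.1f", max(tr$time_s) / 3600), " h), ",
      nrow(x$events), " logged events, seed ", x$seed, "\n", sep = "")
  cat("  final: biomass ", sprintf("%.2f", x$plant$biomass),
      ", glucose ", sprintf("%.3f", x$plant$glucose), " g/L, volume ",
      sprintf("%.3f", x$plant$volume), " L\n", sep = "")
  invisible(x)
}
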