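#' Fed-batch plant parameters
#'
#' A deliberately minimal fed-batch *E. coli* plant model used to exercise
#' the controller in closed loop. Growth follows Monod kinetics on glucose;
#' dissolved oxygen obeys `d(DO)/dt = kLa (DO_sat - DO) - OUR` with the
#' oxygen uptake rate proportional to the glucose uptake rate; feeding adds
#' volume from concentrated stocks. The sensor applies a first-order lag and
#' Gaussian noise to the true DO. Kinetic constants are lumped and scaled to
#' produce DO-stat sawtooth dynamics with spike periods of a few minutes at
#' mid-run; the simulator exercises control logic, it does not predict
#' physiology.
#'
#' @param mu_max maximum specific growth rate (1/h).
#' @param Ks Monod half-saturation constant for glucose (g/L).
#' @param Ko oxygen half-saturation for substrate uptake (\% air
#'   saturation); growth follows dual-Monod kinetics
#'   `mu = mu_max * S/(Ks+S) * DO/(Ko+DO)`, so oxygen transfer bounds the
#'   attainable uptake instead of letting demand grow without limit.
#' @param Yxs biomass yield on glucose (g biomass / g glucose).
#' @param yo lumped oxygen demand: \%DO consumed per (g/L) glucose taken up.
#'   Absorbs the O2-per-glucose yield and the saturation concentration, so
#'   biomass can stay in arbitrary density units.
#' @param kla_a volumetric oxygen transfer coefficient (1/h) at the reference
#'   actuator point (400 rpm, 0.5 L/min).
#' @param kla_b,kla_c exponents of the stirred-tank correlation
#'   `kLa = kla_a * (rpm/400)^kla_b * (air/0.5)^kla_c`, monotone increasing
#'   in both actuators by construction.
#' @param do_sat DO saturation level (\% air saturation).
#' @param initial_glucose starting glucose (g/L).
#' @param initial_biomass starting biomass (arbitrary g/L-equivalent).
#' @param initial_volume starting broth volume (L).
#' @param initial_do starting DO (\%).
#' @param feed_glc_conc glucose concentration of the feed stock (g/L).
#' @param feed_ns_conc yeast-extract concentration of the nitrogen feed
#'   stock (g/L); the nitrogen feed contributes volume only.
#' @param sensor_noise_sd Gaussian sensor noise sd (\%DO).
#' @param sensor_lag_tau first-order sensor lag time constant (s).
#' @return an object of class `plant_params`.
#' @export
plant_params <- function(mu_max = 0.4, Ks = 0.05, Ko = 5, Yxs = 0.5,
                         yo = 2500,
                         kla_a = 120, kla_b = 1.2, kla_c = 0.5,
                         do_sat = 100,
                         initial_glucose = 10, initial_biomass = 0.5,
                         initial_volume = 0.7, initial_do = 100,
                         feed_glc_conc = 500, feed_ns_conc = 100,
                         sensor_noise_sd = 0.3, sensor_lag_tau = 15) {
  p <- list(mu_max = mu_max, Ks = Ks, Ko = Ko, Yxs = Yxs, yo = yo,
            kla_a = kla_a, kla_b = kla_b, kla_c = kla_c, do_sat = do_sat,
            initial_glucose = initial_glucose,
            initial_biomass = initial_biomass,
            initial_volume = initial_volume, initial_do = initial_do,
            feed_glc_conc = feed_glc_conc, feed_ns_conc = feed_ns_conc,
            sensor_noise_sd = sensor_noise_sd,
            sensor_lag_tau = sensor_lag_tau)
  pos <- c("mu_max", "Ks", "Ko", "Yxs", "yo", "kla_a", "kla_b", "kla_c",
           "do_sat",
           "initial_volume", "feed_glc_conc", "feed_ns_conc",
           "sensor_lag_tau")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("'", nm, "' must be positive", call. = FALSE)
  if (p$sensor_noise_sd < 0) stop("'sensor_noise_sd' must be >= 0",
                                  call. = FALSE)
  if (p$initial_glucose < 0 || p$initial_biomass < 0 || p$initial_do < 0 ||
      p$initial_do > 100)
    stop("initial state out of range", call. = FALSE)
  structure(p, class = "plant_params")
}

#' Initial plant state
#'
#' @param params a [plant_params()] object.
#' @return an object of class `plant_state` with fields `biomass`, `glucose`
#'   (g/L), `do_percent` (true DO, \%), `do_meas` (lagged sensor state, \%),
#'   `volume` (L) and `time` (s).
#' @export
init_plant_state <- function(params = plant_params()) {
  structure(list(biomass = params$initial_biomass,
                 glucose = params$initial_glucose,
                 do_percent = params$initial_do,
                 do_meas = params$initial_do,
                 volume = params$initial_volume,
                 time = 0),
            class = "plant_state")
}

kla_value <- function(params, agitate_rpm, air_lpm) {
  params$kla_a * (agitate_rpm / 400)^params$kla_b * (air_lpm / 0.5)^params$kla_c
}

#' Advance the plant by one explicit-Euler step
#'
#' Mass balances are integrated on the extensive scale (mass = concentration
#' x volume) so feed inflow, consumption and dilution are exactly
#' accounted. The sensor reading (lagged, noisy, clipped DO) is updated
#' inside the step and consumes one draw from the R random number generator
#' when `sensor_noise_sd > 0`.
#'
#' @param state a `plant_state`.
#' @param actuators a list with `agitate_rate` (rpm), `air_flow` (L/min),
#'   `glucose_pump_on`, `nitrogen_pump_on` (logical), `glc_feed_rate` and
#'   `ns_feed_rate` (g/L/h, relative to current broth volume); see
#'   [actuator_command()].
#' @param params a [plant_params()].
#' @param dt step size in seconds (<= 1 for stability).
#' @return the updated `plant_state`.
#' @export
step_plant <- function(state, actuators, params = plant_params(), dt = 1) {
  if (dt <= 0 || dt > 1) stop("'dt' must be in (0, 1] seconds", call. = FALSE)
  dth <- dt / 3600
  V <- state$volume; S <- state$glucose; X <- state$biomass
  # volumetric feed flows (L/h): rate is g per L of culture per h
  Fg <- if (isTRUE(actuators$glucose_pump_on))
          actuators$glc_feed_rate * V / params$feed_glc_conc else 0
  Fn <- if (isTRUE(actuators$nitrogen_pump_on))
          actuators$ns_feed_rate * V / params$feed_ns_conc else 0
  mu <- if (S > 0)
          params$mu_max * S / (params$Ks + S) *
            state$do_percent / (params$Ko + state$do_percent)
        else 0
  uptake <- mu / params$Yxs * X                      # g glucose / L / h
  V1 <- V + (Fg + Fn) * dth
  SV1 <- S * V + (Fg * params$feed_glc_conc - uptake * V) * dth
  S1 <- max(SV1 / V1, 0)
  X1 <- (X * V + mu * X * V * dth) / V1
  kla <- kla_value(params, actuators$agitate_rate, actuators$air_flow)
  DO1 <- state$do_percent +
    (kla * (params$do_sat - state$do_percent) - params$yo * uptake) * dth
  DO1 <- min(max(DO1, 0), 100)
  do_meas <- state$do_meas + dt / params$sensor_lag_tau *
    (DO1 - state$do_meas)
  if (params$sensor_noise_sd > 0)
    state$noise_draw <- stats::rnorm(1, 0, params$sensor_noise_sd)
  else
    state$noise_draw <- 0
  st <- structure(list(biomass = X1, glucose = S1, do_percent = DO1,
                       do_meas = do_meas, volume = V1,
                       time = state$time + dt,
                       noise_draw = state$noise_draw),
                  class = "plant_state")
  if (any(!is.finite(c(X1, S1, DO1, V1))))
    stop("plant state became non-finite at t = ", st$time, " s",
         call. = FALSE)
  st
}

#' Current sensor reading of a plant state
#'
#' @param state a `plant_state` (after at least one [step_plant()]).
#' @return lagged, noisy DO reading clipped to \[0, 100\] \%.
#' @export
sensor_reading <- function(state) {
  min(max(state$do_meas + (state$noise_draw %||% 0), 0), 100)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the plant open loop under an actuator schedule
#'
#' @param params a [plant_params()].
#' @param schedule a function `(time_s) -> actuator list` (see
#'   [step_plant()]); defaults to constant initial actuators with no feed.
#' @param duration_h simulated duration (hours).
#' @param seed integer RNG seed (sensor noise).
#' @param dt step size (s).
#' @return a `data.frame` with columns `time_s`, `do_true`, `do_meas`,
#'   `glucose_g_l`, `biomass`, `volume_l`.
#' @export
run_open_loop <- function(params = plant_params(),
                          schedule = NULL, duration_h = 6, seed = 1L,
                          dt = 1) {
  if (is.null(schedule)) {
    schedule <- function(time_s)
      list(agitate_rate = 400, air_flow = 0.5, glucose_pump_on = FALSE,
           nitrogen_pump_on = FALSE, glc_feed_rate = 0, ns_feed_rate = 0)
  }
  set.seed(as.integer(seed))
  n <- ceiling(duration_h * 3600 / dt)
  state <- init_plant_state(params)
  out <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) {
    state <- step_plant(state, schedule(state$time), params, dt)
    out[i, ] <- c(state$time, state$do_percent, sensor_reading(state),
                  state$glucose, state$biomass, state$volume)
  }
  out <- as.data.frame(out)
  names(out) <- c("time_s", "do_true", "do_meas", "glucose_g_l", "biomass",
                  "volume_l")
  out
}
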