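test_that("controller parameter invariants are enforced", {
  expect_error(controller_params(baseline_lb = 50, baseline_ub = 50),
               "baseline_lb")
  expect_error(controller_params(baseline_increase = 40,
                                 threshold_increase = 40),
               "threshold_increase")
  expect_error(controller_params(v_glc = -1), "v_glc")
  expect_error(controller_params(max_pulse_duration = 0),
               "max_pulse_duration")
  p <- controller_params()
  expect_equal(p$baseline_lb, 25)
  expect_equal(p$threshold_increase, 40)
})

test_that("a minute of identical samples aggregates to their value", {
  st <- new_controller_state()
  st <- feed_seconds(st, 0:59, 30)
  expect_length(st$minute_values, 0)  # minute not yet closed
  st <- feed_seconds(st, 60, 30)
  expect_equal(st$minute_values, 30)
  expect_true(st$new_minute)
})

test_that("minute aggregation is the arithmetic mean of the samples", {
  st <- new_controller_state()
  st <- feed_seconds(st, c(0, 30), c(20, 40))
  st <- feed_seconds(st, 60, 50)
  expect_equal(st$minute_values, 30)
})

test_that("the sliding window trims to the most recent 60 minutes", {
  st <- new_controller_state()
  # 62 minutes, each with one sample whose value is the minute index
  st <- feed_seconds(st, seq(0, 62 * 60, by = 60), 0:62)
  expect_length(st$minute_values, 60)
  expect_equal(st$minute_values, as.numeric(2:61))  # oldest minutes dropped
})

test_that("out-of-order samples are rejected", {
  st <- new_controller_state()
  st <- feed_seconds(st, 0:10, 30)
  expect_error(ingest_sample(st, process_sample(5 / 3600, 30, time_s = 5)),
               "out-of-order")
  expect_error(process_sample(1, 150), "0, 100")
})

test_that("baseline updates are skipped during warm-up", {
  st <- new_controller_state()
  st <- feed_seconds(st, 0:(30 * 60), 40)  # only 30 full minutes
  st <- update_baseline(st, function(w) mean(w))
  expect_true(is.na(st$baseline_smooth))
  # and no decision that depends on the baseline fires
  st2 <- decide_glucose_feed(st, controller_params())
  expect_false(st2$feeding_active)
  st3 <- decide_oxygen(st, controller_params())
  expect_equal(st3$agitate_rate, st$agitate_rate)
})

test_that("one baseline update is logged per minute after warm-up", {
  st <- new_controller_state()
  recognizer <- function(w) mean(w)
  for (t in 0:(3 * 3600)) {
    st <- ingest_sample(st, process_sample(t / 3600, 35, time_s = t))
    if (st$new_minute && length(st$minute_values) >= st$window_length)
      st <- update_baseline(st, recognizer)
  }
  ev <- event_log(st)
  n_updates <- sum(ev$event == "baseline_update")
  # 180 minute rollovers in 3 h; the first 59 aggregates are warm-up
  expect_equal(n_updates, 180 - 59)
  expect_equal(st$baseline_smooth, 35, tolerance = 1e-9)
})

test_that("oxygen-supply steps are +/-20 rpm and +/-0.05 L/min, clamped", {
  p <- controller_params()
  # oxygen-deficient: baseline below the lower bound
  st <- warmed_state(20, agitate = 400, air = 0.5)
  st <- decide_oxygen(st, p)
  expect_equal(st$agitate_rate, 420)
  expect_equal(st$air_flow, 0.55)
  # oxygen-excessive: baseline above the upper bound
  st2 <- warmed_state(55, agitate = 420, air = 0.55)
  st2 <- decide_oxygen(st2, p)
  expect_equal(st2$agitate_rate, 400)
  expect_equal(st2$air_flow, 0.5)
  # dead band: no change
  st3 <- warmed_state(35, agitate = 500, air = 0.8)
  st3 <- decide_oxygen(st3, p)
  expect_equal(st3$agitate_rate, 500)
  expect_equal(st3$air_flow, 0.8)
  # clamping at the limits
  st4 <- warmed_state(20, agitate = 800, air = 1.5)
  st4 <- decide_oxygen(st4, p)
  expect_equal(st4$agitate_rate, 800)
  expect_equal(st4$air_flow, 1.5)
  st5 <- warmed_state(55, agitate = 400, air = 0.5)
  st5 <- decide_oxygen(st5, p)
  expect_equal(st5$agitate_rate, 400)
  expect_equal(st5$air_flow, 0.5)
})

test_that("glucose pulses start and stop at the baseline-relative thresholds", {
  p <- controller_params()  # threshold_increase 40, baseline_increase 15
  st <- warmed_state(25, last_do = 66)
  st <- decide_glucose_feed(st, p)
  expect_true(st$feeding_active)   # 66 > 25 + 40
  expect_true(st$glc_pump_on)
  expect_equal(st$glc_feed_rate, 21)
  # boundary is strict: DO exactly at threshold does not trigger
  st2 <- warmed_state(25, last_do = 65)
  st2 <- decide_glucose_feed(st2, p)
  expect_false(st2$feeding_active)
  # stop when DO falls below baseline + baseline_increase
  st$last_do <- 39
  st <- decide_glucose_feed(st, p)
  expect_false(st$feeding_active)  # 39 < 25 + 15
  ev <- event_log(st)
  expect_identical(ev$event[ev$event != "baseline_update"],
                   c("feed_start", "feed_stop"))
})

test_that("a pulse stuck above the stop threshold is forcibly cut at 3 min", {
  p <- controller_params()
  st <- warmed_state(25, last_do = 70)
  st <- decide_glucose_feed(st, p)
  expect_true(st$feeding_active)
  for (i in 1:180) st <- decide_glucose_feed(st, p)  # DO stuck at 70
  expect_false(st$feeding_active)
  ev <- event_log(st)
  expect_equal(sum(ev$event == "feed_forced_stop"), 1)
  expect_lte(ev$detail[ev$event == "feed_forced_stop"],
             p$max_pulse_duration * 60 + 1)
})

test_that("nitrogen feeding latches on at the first glucose trigger", {
  p <- controller_params()
  st <- warmed_state(25, last_do = 50)
  st <- decide_nitrogen_feed(st, p)
  expect_false(st$ns_pump_on)  # before any glucose trigger
  st$last_do <- 66
  st <- decide_glucose_feed(st, p)
  st <- decide_nitrogen_feed(st, p)
  expect_true(st$ns_pump_on)
  expect_equal(st$ns_feed_rate, 1.0)
  # pulse ends, nitrogen stays on
  st$last_do <- 30
  st <- decide_glucose_feed(st, p)
  st <- decide_nitrogen_feed(st, p)
  expect_false(st$glc_pump_on)
  expect_true(st$ns_pump_on)
})

test_that("induction fires once, strictly after induction_time", {
  pp <- phase_param_set()  # induction at 10 h; overrides (5, 10, 7)
  st <- warmed_state(30)
  st$runtime_h <- 9.99
  st <- decide_induction(st, pp)
  expect_false(st$induced)
  expect_equal(st$temperature, 37)
  st$runtime_h <- 10.01
  st <- decide_induction(st, pp)
  expect_true(st$induced)
  expect_equal(st$temperature, 28)
  expect_equal(st$iptg_dose, 0.3)
  expect_identical(st$phase, "induction")
  ap <- active_params(st, pp)
  expect_equal(ap$baseline_increase, 5)
  expect_equal(ap$threshold_increase, 10)
  expect_equal(ap$v_glc, 7)
  # one-shot latch: no second dose later
  st$runtime_h <- 12
  st <- decide_induction(st, pp)
  ev <- event_log(st)
  expect_equal(sum(ev$event == "induction"), 1)
})

test_that("phase parameter sets validate their overrides", {
  expect_error(phase_param_set(induction_overrides = list(bogus = 1)),
               "unknown induction override")
  expect_error(phase_param_set(induction_overrides =
                                 list(baseline_increase = 20,
                                      threshold_increase = 10)),
               "threshold_increase")
  pp <- phase_param_set(controller_params(),
                        induction_overrides = list(baseline_increase = 0,
                                                   threshold_increase = 10,
                                                   v_glc = 7))
  expect_equal(pp$induction$baseline_increase, 0)
  expect_equal(pp$induction$v_glc, 7)
  expect_equal(pp$induction$baseline_lb, pp$growth$baseline_lb)
})
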