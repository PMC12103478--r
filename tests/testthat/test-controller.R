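cfg <- controller_config()

test_that("entry bolus is weight-based and capped", {
  expect_equal(initial_bolus(70), 0.1)  # 0.14 capped
  expect_equal(initial_bolus(50), 0.1)  # exactly at cap
  expect_equal(initial_bolus(40), 0.08)
  expect_error(initial_bolus(0), "positive")
  expect_error(initial_bolus(-3), "positive")
})

test_that("rates quantize to the 0.1 mL/h pump step and clip at the cap", {
  expect_equal(quantize_rate(0.7031), 0.705)
  expect_equal(quantize_rate(0), 0)
  expect_equal(quantize_rate(5), 2)
  expect_error(quantize_rate(-1), "non-negative")
  # quantum follows the concentration
  cfg2 <- controller_config(conc = 0.1)
  expect_equal(quantize_rate(0.7031, cfg2), 0.70)
})

test_that("the hypotension episode walks entry -> second bolus -> titration", {
  st <- controller_state()
  r1 <- step_controller(st, nibp_reading(0, 95, 60, 45), 70, cfg)
  expect_equal(r1$action$bolus, 0.1)
  expect_equal(r1$action$note, "entry-bolus")
  expect_equal(r1$state$mode, "VASOPRESSOR")
  expect_equal(r1$state$infusion_rate, 0)

  r2 <- step_controller(r1$state, nibp_reading(2.5, 92, 58, 41), 70, cfg)
  expect_equal(r2$action$bolus, 0.05)  # half the entry bolus
  expect_equal(r2$action$note, "second-bolus")
  expect_equal(r2$state$infusion_rate, 0.7)  # 0.01 mg/kg/h at 70 kg
  expect_equal(r2$state$boluses_given, 2L)

  # still hypotensive: step-up by 1.25, quantized
  r3 <- step_controller(r2$state, nibp_reading(5, 90, 57, 40), 70, cfg)
  expect_equal(r3$action$note, "step-up")
  expect_equal(r3$state$infusion_rate, quantize_rate(0.7 * 1.25))

  # comfortable band [65, 75): hold
  r4 <- step_controller(r3$state, nibp_reading(7.5, 100, 70, 55), 70, cfg)
  expect_equal(r4$action$note, "hold")
  expect_equal(r4$state$infusion_rate, r3$state$infusion_rate)

  # upper band [75, 85]: step-down by 0.8
  r5 <- step_controller(r4$state, nibp_reading(10, 110, 80, 65), 70, cfg)
  expect_equal(r5$action$note, "step-down")
  expect_equal(r5$state$infusion_rate,
               quantize_rate(r4$state$infusion_rate * 0.8))
})

test_that("MBP above the suspension threshold suspends; recovery resumes", {
  st <- controller_state()
  st$mode <- "VASOPRESSOR"; st$boluses_given <- 2L; st$infusion_rate <- 0.8
  r <- step_controller(st, nibp_reading(10, 125, 90, 72), 70, cfg)
  expect_equal(r$action$note, "suspend")
  expect_equal(r$state$infusion_rate, 0)
  expect_equal(r$state$pre_suspension_rate, 0.8)
  expect_equal(r$state$suspended_since, 10)

  # boundary: MBP exactly 85 maintains (suspension is strict)
  r85 <- step_controller(st, nibp_reading(10, 120, 85, 68), 70, cfg)
  expect_false(r85$action$note == "suspend")

  # resume in-band at the remembered rate (stepped down in the upper band)
  r2 <- step_controller(r$state, nibp_reading(12.5, 105, 78, 63), 70, cfg)
  expect_equal(r2$action$note, "resume")
  expect_equal(r2$state$infusion_rate, quantize_rate(0.8 * 0.8))
  expect_true(is.na(r2$state$suspended_since))
})

test_that("suspension beyond the timeout exits vasopressor mode", {
  st <- controller_state()
  st$mode <- "VASOPRESSOR"; st$boluses_given <- 2L
  st$infusion_rate <- 0; st$pre_suspension_rate <- 0.7
  st$suspended_since <- 5
  # 17.5 min later (> 15): mode resets
  r <- step_controller(st, nibp_reading(22.5, 120, 90, 75), 70, cfg)
  expect_equal(r$state$mode, "NORMAL")
  expect_equal(r$action$note, "exit")
  # exactly 15 min: strict comparison, still in mode
  r15 <- step_controller(st, nibp_reading(20, 120, 90, 75), 70, cfg)
  expect_equal(r15$state$mode, "VASOPRESSOR")
  # hypotensive reading after the timeout re-triggers a full entry bolus
  rh <- step_controller(st, nibp_reading(22.5, 95, 60, 45), 70, cfg)
  expect_equal(rh$action$bolus, 0.1)
  expect_equal(rh$action$note, "entry-bolus")
  expect_equal(rh$state$boluses_given, 1L)
})

test_that("invalid readings freeze the control state", {
  st <- controller_state()
  st$mode <- "VASOPRESSOR"; st$boluses_given <- 2L; st$infusion_rate <- 0.5
  r <- step_controller(st, nibp_reading(30, valid = FALSE), 70, cfg)
  expect_identical(r$state, st)
  expect_equal(r$action$note, "frozen")
  expect_equal(r$action$bolus, 0)
})

test_that("boundary MBP values follow the strict conventions", {
  st <- controller_state()
  # MBP exactly at t_low is adequate: no entry
  r <- step_controller(st, nibp_reading(0, 100, 65, 50), 70, cfg)
  expect_equal(r$state$mode, "NORMAL")
  expect_equal(r$action$bolus, 0)
  r2 <- step_controller(st, nibp_reading(0, 100, 64.999, 50), 70, cfg)
  expect_equal(r2$state$mode, "VASOPRESSOR")
})

test_that("replay is deterministic, ordered, and inert above threshold", {
  set.seed(11)
  traj <- random_trajectory(60)
  a1 <- run_controller(traj, 70, cfg)
  a2 <- run_controller(traj, 70, cfg)
  expect_identical(a1, a2)

  bad <- traj
  bad$t_min[3] <- bad$t_min[2]
  expect_error(run_controller(bad, 70, cfg), "increasing")

  quiet <- traj
  quiet$mbp <- pmax(quiet$mbp, 65)
  quiet$sbp <- pmax(quiet$sbp, quiet$mbp + 5)
  aq <- run_controller(quiet, 70, cfg)
  expect_equal(sum(aq$actions$bolus_mg), 0)
  expect_equal(sum(aq$actions$rate_mg_h), 0)
  expect_equal(aq$state$mode, "NORMAL")
})

test_that("bolus emissions tally with an independent mode-entry recount", {
  set.seed(23)
  for (rep in 1:20) {
    traj <- random_trajectory(80)
    log <- run_controller(traj, 70, cfg)$actions
    n_bolus <- sum(log$bolus_mg > 0)
    expect_equal(n_bolus,
                 sum(log$note == "entry-bolus") +
                   sum(log$note == "second-bolus"))
    ref <- expected_boluses(traj, cfg)
    expect_equal(sum(log$note == "entry-bolus"), ref$entries)
    expect_equal(sum(log$note == "second-bolus"), ref$seconds)
  }
})
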