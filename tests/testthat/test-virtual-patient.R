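quiet_profile <- function(...) {
  patient_profile(noise_sd = 0, fail_prob = 0, ...)
}

test_that("true MBP composes baseline, anesthetic drop and disturbances", {
  p <- quiet_profile(mbp_baseline = 95, anesthetic_drop = 18, onset_tau = 5)
  # induction plateau: baseline minus full drop
  expect_equal(true_mbp(200, p), 95 - 18, tolerance = 1e-9)
  # disturbance active on [onset, onset + duration)
  pd <- quiet_profile(disturbances = data.frame(onset = 50, depth = 20,
                                                duration = 30))
  expect_equal(true_mbp(60, pd), true_mbp(60, quiet_profile()) - 20)
  expect_equal(true_mbp(81, pd), true_mbp(81, quiet_profile()))
})

test_that("bolus effect matches the closed-form one-compartment solution", {
  p <- quiet_profile(ke = 0.2, emax = 25, c50 = 0.05)
  d <- drug_record(boluses = data.frame(t = 0, dose = 0.1))
  eff <- function(t) true_mbp(t, p, d) - true_mbp(t, p, drug_record())
  expect_equal(eff(0), 25 * 0.1 / 0.15, tolerance = 1e-9)
  for (t in c(1, 2.5, 5, 10, 20)) {
    amt <- 0.1 * exp(-0.2 * t)
    expect_equal(eff(t), 25 * amt / (0.05 + amt), tolerance = 1e-9)
  }
})

test_that("constant infusion approaches the analytic steady state", {
  p <- quiet_profile(ke = 0.2, emax = 25, c50 = 0.05)
  r <- 0.7 # mg/h
  d <- drug_record(infusion_segments = data.frame(start = 0, end = 500,
                                                  rate = r))
  css <- (r / 60) / 0.2
  eff_ss <- 25 * css / (0.05 + css)
  eff <- true_mbp(400, p, d) - true_mbp(400, p, drug_record())
  expect_equal(eff, eff_ss, tolerance = 1e-9)
})

test_that("PK agrees with numeric ODE integration on a mixed schedule", {
  skip_if_not_installed("deSolve")
  ke <- 0.17
  d <- drug_record(
    boluses = data.frame(t = c(0, 12.5), dose = c(0.1, 0.05)),
    infusion_segments = data.frame(start = c(12.5, 40), end = c(30, 55),
                                   rate = c(0.7, 1.1))
  )
  rate_in <- function(t) { # mg/min
    s <- d$infusion_segments
    hit <- s$start <= t & t < s$end
    if (any(hit)) sum(s$rate[hit]) / 60 else 0
  }
  deriv <- function(t, y, parms) list(rate_in(t) - ke * y)
  times <- seq(0, 80, by = 0.05)
  num <- deSolve::lsoda(c(C = 0), times, deriv, NULL, rtol = 1e-10,
                        atol = 1e-12,
                        events = list(data = data.frame(
                          var = "C", time = c(0, 12.5),
                          value = c(0.1, 0.05), method = "add")))
  p <- quiet_profile(ke = ke)
  for (t in c(5, 12.6, 20, 30, 45, 60, 80)) {
    analytic <- pressorloop:::effect_site_amount(t, p, d)
    numeric <- num[which.min(abs(num[, "time"] - t)), "C"]
    expect_equal(analytic, unname(numeric), tolerance = 1e-6)
  }
})

test_that("PK is linear (superposition) and washes out", {
  p <- quiet_profile()
  b1 <- drug_record(boluses = data.frame(t = 5, dose = 0.08))
  b2 <- drug_record(boluses = data.frame(t = 20, dose = 0.05))
  both <- drug_record(boluses = data.frame(t = c(5, 20),
                                           dose = c(0.08, 0.05)))
  amt <- pressorloop:::effect_site_amount
  for (t in c(6, 21, 40))
    expect_equal(amt(t, p, both), amt(t, p, b1) + amt(t, p, b2),
                 tolerance = 1e-12)
  # washout: effect-site amount vanishes long after the last dose
  expect_lt(amt(300, p, both), 1e-12)
})

test_that("more drug never lowers the simulated pressure", {
  p <- quiet_profile()
  low <- drug_record(boluses = data.frame(t = 0, dose = 0.05))
  high <- drug_record(boluses = data.frame(t = 0, dose = 0.1))
  for (t in c(0, 2.5, 10, 30))
    expect_gte(true_mbp(t, p, high), true_mbp(t, p, low))
})

test_that("measurement model honors noise, failure and ordering contracts", {
  p <- quiet_profile()
  set.seed(4)
  r <- measure_nibp(30, p, drug_record())
  expect_equal(r$mbp, true_mbp(30, p, drug_record()))
  expect_true(r$dbp < r$mbp && r$mbp < r$sbp)

  pf <- patient_profile(fail_prob = 0.999999)
  set.seed(4)
  expect_false(measure_nibp(10, pf)$valid)

  pn <- patient_profile(noise_sd = 4, fail_prob = 0.05)
  set.seed(99); a <- replicate(20, measure_nibp(10, pn)$mbp)
  set.seed(99); b <- replicate(20, measure_nibp(10, pn)$mbp)
  expect_identical(a, b)
})

test_that("cohorts are seed-deterministic with bounded durations", {
  c1 <- sample_cohort(20, seed = 5)
  c2 <- sample_cohort(20, seed = 5)
  expect_identical(c1, c2)
  c3 <- sample_cohort(20, seed = 6)
  expect_false(identical(c1, c3))
  expect_true(all(c1$durations >= 90 & c1$durations <= 360))
  expect_true(all(sapply(c1$profiles, `[[`, "weight") > 40))
  # zero variability collapses to identical profiles
  c0 <- sample_cohort(3, seed = 5, variability = 0)
  expect_identical(c0$profiles[[1]], c0$profiles[[2]])
  expect_error(sample_cohort(0), "positive")
})

test_that("closed-loop arms behave per their treatment policy", {
  base <- list(mbp_baseline = 95, anesthetic_drop = 10, noise_sd = 0,
               fail_prob = 0)
  p_ok <- do.call(patient_profile, base) # floor 85: never hypotensive
  set.seed(2)
  su <- run_closed_loop(p_ok, duration = 60, arm = "untreated")
  expect_equal(endpoint_percentages(classify_epochs(su$trajectory))$hypo_pct,
               0)
  expect_equal(nrow(su$drug$boluses), 0)

  p_dip <- patient_profile(noise_sd = 0, fail_prob = 0,
                           disturbances = data.frame(onset = 20, depth = 25,
                                                     duration = 40))
  set.seed(2)
  sa <- run_closed_loop(p_dip, duration = 90, arm = "automated")
  expect_gte(nrow(sa$drug$boluses), 1)
  expect_gte(nrow(sa$drug$infusion_segments), 1)
  # untreated arm on the same patient receives nothing
  set.seed(2)
  s0 <- run_closed_loop(p_dip, duration = 90, arm = "untreated")
  expect_equal(nrow(s0$drug$boluses), 0)
  expect_equal(nrow(s0$drug$infusion_segments), 0)
  # manual-like arm boluses but never infuses
  set.seed(2)
  sm <- run_closed_loop(p_dip, duration = 90, arm = "manual-like")
  expect_gte(nrow(sm$drug$boluses), 1)
  expect_equal(nrow(sm$drug$infusion_segments), 0)
})
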