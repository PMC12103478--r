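#' Virtual-patient profile
#'
#' Parameters of a synthetic intraoperative patient used to exercise the
#' closed loop. The simulator is a test harness, not a physiological claim:
#' mean blood pressure is an additive composition of an awake baseline, an
#' anesthetic depression with exponential onset, rectangular hypotensive
#' disturbances, and a saturating pressor effect driven by a one-compartment
#' drug amount.
#'
#' @param weight Body mass (kg).
#' @param mbp_baseline Awake mean pressure (mmHg).
#' @param anesthetic_drop Steady-state MBP depression under anesthesia
#'   (mmHg), approached with time constant `onset_tau`.
#' @param onset_tau Time constant of anesthetic onset (min).
#' @param disturbances Data frame with columns `onset` (min), `depth` (mmHg)
#'   and `duration` (min): additional MBP depressions active on
#'   `[onset, onset + duration)`.
#' @param pp0,pp1 Pulse-pressure model: `sbp = mbp + pp0 + pp1 * mbp`, and
#'   `dbp` chosen so that `mbp = dbp + (sbp - dbp) / 3`.
#' @param ke Drug elimination rate constant (1/min).
#' @param emax Maximal pressor effect (mmHg).
#' @param c50 Effect-site amount at half-maximal effect (mg).
#' @param noise_sd NIBP measurement noise SD (mmHg).
#' @param fail_prob Probability that a cuff measurement fails.
#' @return A list of class `patient_profile`.
#' @export
#' @examples
#' patient_profile(disturbances = data.frame(onset = 30, depth = 20,
#'                                           duration = 25))
patient_profile <- function(weight = 65, mbp_baseline = 95,
                            anesthetic_drop = 18, onset_tau = 5,
                            disturbances = empty_disturbances(),
                            pp0 = 25, pp1 = 0.25,
                            ke = 0.2, emax = 25, c50 = 0.05,
                            noise_sd = 3, fail_prob = 0.02) {
  stopifnot(weight > 0, ke > 0, emax >= 0, c50 > 0,
            fail_prob >= 0, fail_prob < 1, noise_sd >= 0, onset_tau > 0)
  disturbances <- as.data.frame(disturbances)
  if (nrow(disturbances) &&
      !all(c("onset", "depth", "duration") %in% names(disturbances)))
    stop("disturbances need columns onset, depth, duration", call. = FALSE)
  structure(list(weight = weight, mbp_baseline = mbp_baseline,
                 anesthetic_drop = anesthetic_drop, onset_tau = onset_tau,
                 disturbances = disturbances, pp0 = pp0, pp1 = pp1,
                 ke = ke, emax = emax, c50 = c50,
                 noise_sd = noise_sd, fail_prob = fail_prob),
            class = "patient_profile")
}

empty_disturbances <- function() {
  data.frame(onset = numeric(0), depth = numeric(0), duration = numeric(0))
}

#' Dosing history record
#'
#' @param boluses Data frame with columns `t` (min) and `dose` (mg).
#' @param infusion_segments Data frame with columns `start`, `end` (min) and
#'   `rate` (mg/h); segments must be time-ordered and non-overlapping.
#' @return A list of class `drug_record`.
#' @export
drug_record <- function(boluses = data.frame(t = numeric(0),
                                             dose = numeric(0)),
                        infusion_segments = data.frame(start = numeric(0),
                                                       end = numeric(0),
                                                       rate = numeric(0))) {
  boluses <- as.data.frame(boluses)
  infusion_segments <- as.data.frame(infusion_segments)
  if (nrow(boluses) && any(boluses$dose < 0))
    stop("bolus doses must be non-negative", call. = FALSE)
  if (nrow(infusion_segments)) {
    seg <- infusion_segments
    if (any(seg$rate < 0) || any(seg$end < seg$start))
      stop("infusion segments need rate >= 0 and end >= start", call. = FALSE)
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)] - 1e-9))
      stop("infusion segments must be non-overlapping and ordered",
           call. = FALSE)
  }
  structure(list(boluses = boluses, infusion_segments = infusion_segments),
            class = "drug_record")
}

# One-compartment effect-site amount (mg) at time t. Linear PK: boluses decay
# as dose * exp(-ke (t - tb)); an infusion segment at r mg/h contributes
# (r/60)/ke * (1 - exp(-ke * dt)) while running, carried forward with decay.
effect_site_amount <- function(t, profile, drug) {
  ke <- profile$ke
  amt <- 0
  b <- drug$boluses
  if (nrow(b)) {
    active <- b$t <= t
    amt <- amt + sum(b$dose[active] * exp(-ke * (t - b$t[active])))
  }
  s <- drug$infusion_segments
  if (nrow(s)) {
    for (i in seq_len(nrow(s))) {
      if (s$start[i] >= t) next
      dt <- min(t, s$end[i]) - s$start[i]
      built <- (s$rate[i] / 60) / ke * (1 - exp(-ke * dt))
      decay <- if (t > s$end[i]) exp(-ke * (t - s$end[i])) else 1
      amt <- amt + built * decay
    }
  }
  amt
}

#' True (noise-free) mean blood pressure of a virtual patient
#'
#' `mbp_baseline - drop(t) - sum(active disturbance depths) +
#' emax * C(t) / (c50 + C(t))`, with `C(t)` the one-compartment effect-site
#' amount of all boluses and infusion segments given so far. Deterministic.
#'
#' @param t Time (min, scalar or vector).
#' @param profile A [patient_profile()].
#' @param drug A [drug_record()].
#' @return MBP (mmHg), same length as `t`.
#' @export
#' @examples
#' p <- patient_profile(noise_sd = 0, fail_prob = 0)
#' true_mbp(60, p, drug_record()) # baseline minus anesthetic drop
true_mbp <- function(t, profile, drug = drug_record()) {
  stopifnot(all(t >= 0))
  vapply(t, function(tt) {
    drop <- profile$anesthetic_drop * (1 - exp(-tt / profile$onset_tau))
    d <- profile$disturbances
    dist <- if (nrow(d))
      sum(d$depth[d$onset <= tt & tt < d$onset + d$duration]) else 0
    amt <- effect_site_amount(tt, profile, drug)
    eff <- profile$emax * amt / (profile$c50 + amt)
    profile$mbp_baseline - drop - dist + eff
  }, numeric(1))
}

#' Simulate one NIBP measurement
#'
#' With probability `fail_prob` the cuff fails and an invalid reading is
#' returned. Otherwise Gaussian noise is added to the true MBP, SBP is
#' derived through the pulse-pressure model with its own noise term, and DBP
#' closes the standard identity `mbp = dbp + (sbp - dbp)/3`. The SBP draw is
#' resampled if the ordering `sbp > mbp` would be violated; pressures are
#' kept inside (0, 300).
#'
#' Uses the current R RNG stream; seed outside for reproducibility.
#'
#' @param t Measurement time (min).
#' @param profile A [patient_profile()].
#' @param drug A [drug_record()].
#' @return A [nibp_reading()].
#' @export
measure_nibp <- function(t, profile, drug = drug_record()) {
  if (stats::runif(1) < profile$fail_prob)
    return(nibp_reading(t, valid = FALSE))
  mbp <- true_mbp(t, profile, drug) + stats::rnorm(1, 0, profile$noise_sd)
  mbp <- min(max(mbp, 1), 299)
  repeat {
    sbp <- mbp + profile$pp0 + profile$pp1 * mbp +
      stats::rnorm(1, 0, profile$noise_sd)
    if (sbp > mbp) break
  }
  sbp <- min(sbp, 299)
  dbp <- (3 * mbp - sbp) / 2
  dbp <- max(dbp, 0.5)
  nibp_reading(t, sbp = sbp, mbp = mbp, dbp = dbp, valid = TRUE)
}

#' Run one virtual patient through the closed loop
#'
#' Simulates NIBP measurements every `config$interval` minutes over
#' `duration` minutes and applies the treatment policy of the chosen arm:
#' \describe{
#'   \item{`"automated"`}{each reading is fed to [step_controller()]; its
#'     bolus and infusion-rate actions are written into the drug record and
#'     feed back into the simulated pressure.}
#'   \item{`"untreated"`}{no drug is ever given.}
#'   \item{`"manual-like"`}{a caricature of a busy anesthesiologist: each
#'     hypotensive reading triggers the entry bolus only, delayed by one
#'     epoch with probability `manual_delay_prob`, with no infusion
#'     titration.}
#' }
#'
#' @param profile A [patient_profile()].
#' @param config A [controller_config()].
#' @param duration Case length (min).
#' @param arm One of `"automated"`, `"untreated"`, `"manual-like"`.
#' @param manual_delay_prob Probability the manual-like bolus arrives one
#'   epoch late. Default 0.5.
#' @return List with `trajectory` (data frame `t_min, sbp, mbp, dbp, valid`),
#'   `drug` (a [drug_record()]), and `actions` (controller action log;
#'   empty outside the automated arm).
#' @export
#' @examples
#' set.seed(1)
#' p <- patient_profile(disturbances = data.frame(onset = 20, depth = 25,
#'                                                duration = 40))
#' sim <- run_closed_loop(p, duration = 90, arm = "automated")
#' sum(sim$drug$boluses$dose)
run_closed_loop <- function(profile, config = controller_config(),
                            duration = 180,
                            arm = c("automated", "untreated", "manual-like"),
                            manual_delay_prob = 0.5) {
  arm <- match.arg(arm)
  stopifnot(duration > 0)
  times <- seq(0, duration, by = config$interval)
  n <- length(times)

  boluses <- data.frame(t = numeric(0), dose = numeric(0))
  segs <- data.frame(start = numeric(0), end = numeric(0), rate = numeric(0))
  cur_rate <- 0
  cur_start <- NA_real_
  state <- controller_state()
  pending_bolus <- NULL # manual-like arm: c(t, dose)

  traj <- data.frame(t_min = times, sbp = NA_real_, mbp = NA_real_,
                     dbp = NA_real_, valid = 0L)
  log <- empty_action_log()

  set_rate <- function(rate, t) {
    if (isTRUE(all.equal(rate, cur_rate))) return()
    if (cur_rate > 0)
      segs[nrow(segs) + 1, ] <<- c(cur_start, t, cur_rate)
    cur_rate <<- rate
    cur_start <<- t
  }

  for (i in seq_len(n)) {
    t <- times[i]
    if (!is.null(pending_bolus) && pending_bolus[1] <= t) {
      boluses[nrow(boluses) + 1, ] <- pending_bolus
      pending_bolus <- NULL
    }
    drug <- drug_record(boluses, close_segments(segs, cur_rate, cur_start, t))
    reading <- measure_nibp(t, profile, drug)
    traj$sbp[i] <- reading$sbp
    traj$mbp[i] <- reading$mbp
    traj$dbp[i] <- reading$dbp
    traj$valid[i] <- as.integer(reading$valid)

    if (arm == "automated") {
      res <- step_controller(state, reading, profile$weight, config)
      state <- res$state
      if (res$action$bolus > 0)
        boluses[nrow(boluses) + 1, ] <- c(t, res$action$bolus)
      set_rate(res$action$rate_setpoint, t)
      log[nrow(log) + 1, ] <- list(t, res$action$bolus,
                                   res$action$rate_setpoint,
                                   res$action$rate_setpoint / config$conc,
                                   state$mode, res$action$note)
    } else if (arm == "manual-like") {
      if (reading$valid && reading$mbp < config$t_low &&
          is.null(pending_bolus)) {
        dose <- initial_bolus(profile$weight, config)
        if (stats::runif(1) < manual_delay_prob) {
          pending_bolus <- c(t + config$interval, dose)
        } else {
          boluses[nrow(boluses) + 1, ] <- c(t, dose)
        }
      }
    }
  }
  segs <- close_segments(segs, cur_rate, cur_start, times[n])
  list(trajectory = traj, drug = drug_record(boluses, segs), actions = log)
}

# append the currently-open infusion segment (if any) up to time t
close_segments <- function(segs, cur_rate, cur_start, t) {
  if (cur_rate > 0 && !is.na(cur_start) && t > cur_start)
    segs[nrow(segs) + 1, ] <- c(cur_start, t, cur_rate)
  segs
}

#' Draw a cohort of virtual patients
#'
#' Samples patient profiles from documented distributions: weight
#' Normal(65, 12) truncated above 40 kg, awake baseline Normal(95, 10),
#' anesthetic drop Normal(18, 4) truncated above 5, one to five hypotensive
#' disturbances per case with depth Uniform(5, 25) mmHg and duration
#' Uniform(5, 40) min, and case length Uniform(90, 360) min. All spreads
#' scale with `variability` (0 gives identical patients at the means).
#'
#' @param n Number of patients (positive).
#' @param seed RNG seed; the cohort is a deterministic function of
#'   `(n, seed, variability)`.
#' @param variability Scale factor on every spread. Default 1.
#' @return List with `profiles` (list of [patient_profile()]) and
#'   `durations` (numeric vector, min).
#' @export
#' @examples
#' co <- sample_cohort(3, seed = 42)
#' sapply(co$profiles, `[[`, "weight")
sample_cohort <- function(n, seed = 1, variability = 1) {
  if (!is.numeric(n) || n <= 0) stop("n must be positive", call. = FALSE)
  n <- as.integer(n)
  v <- variability
  stopifnot(v >= 0)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  rtnorm <- function(k, mean, sd, lower) {
    x <- stats::rnorm(k, mean, sd)
    while (any(bad <- x <= lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  weights <- rtnorm(n, 65, 12 * v, 40)
  baselines <- stats::rnorm(n, 95, 10 * v)
  drops <- rtnorm(n, 18, 4 * v, 5)
  durations <- if (v == 0) rep(225, n)
               else stats::runif(n, 225 - 135 * v, 225 + 135 * v)

  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    k <- if (v == 0) 3L else sample(1:5, 1)
    dist <- data.frame(
      onset = if (v == 0) seq(30, durations[i] - 30, length.out = k)
              else sort(stats::runif(k, 10, durations[i] - 20)),
      depth = if (v == 0) rep(15, k) else stats::runif(k, 5, 25),
      duration = if (v == 0) rep(20, k) else stats::runif(k, 5, 40)
    )
    profiles[[i]] <- patient_profile(weight = weights[i],
                                     mbp_baseline = baselines[i],
                                     anesthetic_drop = drops[i],
                                     disturbances = dist)
  }
  list(profiles = profiles, durations = durations)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
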