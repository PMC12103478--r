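#' Controller configuration
#'
#' Builds the parameter set of the lower-limit phenylephrine controller.
#' All pressures are in mmHg, times in minutes, doses in mg, rates in mg/h.
#'
#' The controller implements lower-limit (threshold) control: it does not
#' track a set-point, it acts only when mean blood pressure (MBP) falls below
#' `t_low`. On entry into vasopressor mode it gives a weight-based bolus
#' (capped at `bolus_cap`); if hypotension persists at the next reading it
#' gives half that bolus and starts a continuous infusion, which is then
#' titrated once per NIBP epoch by `rate_policy`. Infusion is suspended above
#' `t_suspend`, and a suspension longer than `exit_timeout` ends vasopressor
#' mode entirely.
#'
#' @param t_low Hypotension threshold on MBP; readings strictly below it are
#'   hypotensive. Default 65.
#' @param t_suspend Suspension threshold on MBP; readings strictly above it
#'   suspend the infusion. Default 85.
#' @param t_hyper Hypertension classification threshold on SBP (strictly
#'   above). Default 140. Classification only; the controller never treats
#'   hypertension.
#' @param bolus_per_kg Entry bolus per kg body weight (mg/kg). Default 0.002.
#' @param bolus_cap Maximum single automated bolus (mg). Default 0.1.
#' @param exit_timeout Suspension duration (min, strict) after which the
#'   controller exits vasopressor mode. Default 15.
#' @param interval Nominal NIBP epoch length (min). Default 2.5.
#' @param rate_cap Maximum continuous infusion rate (mg/h). Default 2.
#' @param conc Drug concentration of the syringe solution (mg/mL). Default
#'   0.05. Sets the pump-step quantum: 0.1 mL/h pump resolution equals
#'   `0.1 * conc` mg/h.
#' @param rate_policy List with elements `r0_per_kg` (initial infusion rate,
#'   mg/kg/h), `step_up` (multiplier when still hypotensive), `step_down`
#'   (multiplier in the upper comfort band), `band_low` (MBP at which
#'   step-down begins) and `floor_frac` (lower bound on the rate as a
#'   fraction of the initial rate).
#'
#' @return A list of class `controller_config`.
#' @export
#' @examples
#' cfg <- controller_config()
#' cfg$t_low
controller_config <- function(t_low = 65, t_suspend = 85, t_hyper = 140,
                              bolus_per_kg = 0.002, bolus_cap = 0.1,
                              exit_timeout = 15, interval = 2.5,
                              rate_cap = 2, conc = 0.05,
                              rate_policy = list(r0_per_kg = 0.01,
                                                 step_up = 1.25,
                                                 step_down = 0.8,
                                                 band_low = 75,
                                                 floor_frac = 0.2)) {
  defaults <- list(r0_per_kg = 0.01, step_up = 1.25, step_down = 0.8,
                   band_low = 75, floor_frac = 0.2)
  rate_policy <- utils::modifyList(defaults, as.list(rate_policy))
  cfg <- list(t_low = t_low, t_suspend = t_suspend, t_hyper = t_hyper,
              bolus_per_kg = bolus_per_kg, bolus_cap = bolus_cap,
              exit_timeout = exit_timeout, interval = interval,
              rate_cap = rate_cap, conc = conc, rate_policy = rate_policy)
  class(cfg) <- "controller_config"
  validate_controller_config(cfg)
  cfg
}

validate_controller_config <- function(cfg) {
  stopifnot(
    "thresholds must be positive" =
      all(c(cfg$t_low, cfg$t_suspend, cfg$t_hyper) > 0),
    "t_low must be below t_suspend" = cfg$t_low < cfg$t_suspend,
    "rate_cap must be positive" = cfg$rate_cap > 0,
    "bolus_cap must be positive" = cfg$bolus_cap > 0,
    "conc must be positive" = cfg$conc > 0,
    "interval must be positive" = cfg$interval > 0,
    "exit_timeout must be positive" = cfg$exit_timeout > 0
  )
  rp <- cfg$rate_policy
  stopifnot(
    "rate_policy$r0_per_kg must be positive" = rp$r0_per_kg > 0,
    "rate_policy$step_up must be > 1" = rp$step_up > 1,
    "rate_policy$step_down must be in (0, 1]" =
      rp$step_down > 0 && rp$step_down <= 1,
    "rate_policy$band_low must lie in [t_low, t_suspend]" =
      rp$band_low >= cfg$t_low && rp$band_low <= cfg$t_suspend,
    "rate_policy$floor_frac must be in (0, 1]" =
      rp$floor_frac > 0 && rp$floor_frac <= 1
  )
  invisible(cfg)
}

#' One NIBP reading
#'
#' A single oscillometric cuff measurement. Invalid readings (cuff failure,
#' artifact) carry `valid = FALSE` and their pressures are ignored downstream.
#'
#' @param t Time since evaluation start (min, non-negative).
#' @param sbp,mbp,dbp Systolic / mean / diastolic pressure (mmHg).
#' @param valid Measurement-success flag.
#' @return A list of class `nibp_reading`.
#' @export
#' @examples
#' nibp_reading(0, sbp = 110, mbp = 80, dbp = 65)
nibp_reading <- function(t, sbp = NA_real_, mbp = NA_real_, dbp = NA_real_,
                         valid = TRUE) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("reading time must be a single non-negative number", call. = FALSE)
  if (isTRUE(valid)) {
    if (anyNA(c(sbp, mbp, dbp)))
      stop("a valid reading needs sbp, mbp and dbp", call. = FALSE)
    if (!(dbp <= mbp && mbp <= sbp))
      stop("pressure ordering violated: need dbp <= mbp <= sbp",
           call. = FALSE)
    if (any(c(sbp, mbp, dbp) <= 0) || any(c(sbp, mbp, dbp) >= 300))
      stop("pressures must lie in (0, 300) mmHg", call. = FALSE)
  }
  structure(list(t = t, sbp = sbp, mbp = mbp, dbp = dbp,
                 valid = isTRUE(valid)),
            class = "nibp_reading")
}

#' Initial controller state
#'
#' The controller's entire memory: its mode, the number of automated boluses
#' given in the current vasopressor episode, the running infusion rate, the
#' rate to restore on resumption, and the time the infusion was suspended.
#'
#' @return A list of class `controller_state` in NORMAL mode.
#' @export
controller_state <- function() {
  structure(list(mode = "NORMAL", boluses_given = 0L, infusion_rate = 0,
                 pre_suspension_rate = 0, suspended_since = NA_real_),
            class = "controller_state")
}

validate_controller_state <- function(state, cfg) {
  ok <- is.list(state) &&
    state$mode %in% c("NORMAL", "VASOPRESSOR") &&
    state$boluses_given %in% 0:2 &&
    is.numeric(state$infusion_rate) &&
    state$infusion_rate >= 0 && state$infusion_rate <= cfg$rate_cap
  if (!ok) stop("invalid controller state", call. = FALSE)
  if (state$mode == "NORMAL" &&
      (state$infusion_rate != 0 || state$boluses_given != 0L))
    stop("NORMAL mode requires zero infusion rate and zero boluses",
         call. = FALSE)
  if (!is.na(state$suspended_since) &&
      (state$mode != "VASOPRESSOR" || state$infusion_rate != 0))
    stop("suspension clock only runs in VASOPRESSOR mode at zero rate",
         call. = FALSE)
  invisible(state)
}

#' @export
print.controller_state <- function(x, ...) {
  cat(sprintf("<controller_state> mode=%s boluses=%d rate=%.3f mg/h%s\n",
              x$mode, x$boluses_given, x$infusion_rate,
              if (!is.na(x$suspended_since))
                sprintf(" (suspended since t=%.1f)", x$suspended_since)
              else ""))
  invisible(x)
}

#' Weight-based entry bolus
#'
#' The bolus commanded on entry into vasopressor mode:
#' `min(bolus_per_kg * weight, bolus_cap)` — 0.002 mg/kg capped at 0.1 mg
#' under the defaults.
#'
#' @param weight Body mass (kg, positive).
#' @param config A [controller_config()].
#' @return Bolus dose (mg).
#' @export
#' @examples
#' initial_bolus(70) # capped at 0.1
#' initial_bolus(40) # 0.08
initial_bolus <- function(weight, config = controller_config()) {
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight <= 0)
    stop("weight must be a single positive number", call. = FALSE)
  min(config$bolus_per_kg * weight, config$bolus_cap)
}

#' Quantize an infusion rate to the pump step
#'
#' Syringe pumps accept rates in 0.1 mL/h steps; at concentration `conc`
#' mg/mL that is a quantum of `0.1 * conc` mg/h (0.005 mg/h at the default
#' 0.05 mg/mL). Rounds to the nearest step, then clips to `[0, rate_cap]`.
#'
#' @param rate Requested rate (mg/h, non-negative).
#' @param config A [controller_config()].
#' @return Quantized, capped rate (mg/h).
#' @export
#' @examples
#' quantize_rate(0.7031) # 0.705
quantize_rate <- function(rate, config = controller_config()) {
  if (!is.numeric(rate) || anyNA(rate) || any(rate < 0))
    stop("rate must be non-negative", call. = FALSE)
  step <- 0.1 * config$conc
  pmin(pmax(round(rate / step) * step, 0), config$rate_cap)
}

# Band-adjust a running infusion rate given the current MBP; returns the new
# (quantized, capped, floored) rate. r0 is the episode's initial rate.
adjust_rate <- function(rate, mbp, r0, config) {
  rp <- config$rate_policy
  new <- if (mbp < config$t_low) {
    rate * rp$step_up
  } else if (mbp < rp$band_low) {
    rate
  } else {
    max(rate * rp$step_down, rp$floor_frac * r0)
  }
  quantize_rate(new, config)
}

#' Advance the controller by one NIBP reading
#'
#' The deterministic transition function of the lower-limit control state
#' machine. It is pure: the same `(state, reading, weight, config)` always
#' yields the same `(state, action)` pair.
#'
#' Transition rules, applied in order:
#' \itemize{
#'   \item An invalid reading never changes the state (`note = "frozen"`).
#'   \item NORMAL and MBP < `t_low`: enter vasopressor mode and give the
#'     entry bolus (`"entry-bolus"`).
#'   \item A suspension longer than `exit_timeout` resets the mode to NORMAL;
#'     the same reading is then handled under NORMAL rules, so a hypotensive
#'     reading at that instant immediately re-triggers a full entry bolus.
#'   \item Vasopressor mode, one bolus given, MBP < `t_low`: give half the
#'     entry bolus and start the infusion at the policy's initial rate
#'     (`"second-bolus"`).
#'   \item Vasopressor mode with the infusion running (or suspended): MBP
#'     above `t_suspend` suspends (rate 0, clock starts, `"suspend"`);
#'     otherwise the rate is maintained, stepped up below `t_low`, or stepped
#'     down in the upper band, resuming from the remembered rate if it was
#'     suspended (`"step-up"` / `"hold"` / `"step-down"` / `"resume"`).
#' }
#' Boundary conventions are strict: MBP equal to `t_low` is adequate, MBP
#' equal to `t_suspend` maintains the infusion.
#'
#' @param state A [controller_state()].
#' @param reading A [nibp_reading()].
#' @param weight Body mass (kg).
#' @param config A [controller_config()].
#' @return List with elements `state` (new state) and `action` (list with
#'   `bolus` mg, `rate_setpoint` mg/h, `note`).
#' @export
#' @examples
#' st <- controller_state()
#' step_controller(st, nibp_reading(0, 95, 60, 45), weight = 70)$action
step_controller <- function(state, reading, weight,
                            config = controller_config()) {
  validate_controller_state(state, config)
  if (!inherits(reading, "nibp_reading"))
    stop("reading must be an nibp_reading", call. = FALSE)
  if (!is.numeric(weight) || weight <= 0)
    stop("weight must be positive", call. = FALSE)

  act <- function(bolus = 0, rate = state$infusion_rate, note = "none")
    list(bolus = bolus, rate_setpoint = rate, note = note)

  if (!reading$valid)
    return(list(state = state, action = act(note = "frozen")))

  mbp <- reading$mbp
  r0 <- quantize_rate(config$rate_policy$r0_per_kg * weight, config)

  # suspension timeout: reset, then treat the reading as arriving in NORMAL
  exited <- FALSE
  if (state$mode == "VASOPRESSOR" && !is.na(state$suspended_since) &&
      reading$t - state$suspended_since > config$exit_timeout) {
    state <- controller_state()
    exited <- TRUE
  }

  if (state$mode == "NORMAL") {
    if (mbp < config$t_low) {
      bolus <- initial_bolus(weight, config)
      new <- structure(list(mode = "VASOPRESSOR", boluses_given = 1L,
                            infusion_rate = 0, pre_suspension_rate = 0,
                            suspended_since = NA_real_),
                       class = "controller_state")
      return(list(state = new, action = act(bolus = bolus, rate = 0,
                                            note = "entry-bolus")))
    }
    return(list(state = state,
                action = act(rate = 0,
                             note = if (exited) "exit" else "none")))
  }

  # VASOPRESSOR mode -----------------------------------------------------
  if (state$boluses_given == 1L && mbp < config$t_low) {
    bolus <- initial_bolus(weight, config) / 2
    new <- state
    new$boluses_given <- 2L
    new$infusion_rate <- r0
    new$pre_suspension_rate <- 0
    new$suspended_since <- NA_real_
    return(list(state = new, action = act(bolus = bolus, rate = r0,
                                          note = "second-bolus")))
  }

  suspended <- !is.na(state$suspended_since)
  running <- if (suspended) state$pre_suspension_rate else state$infusion_rate

  if (mbp > config$t_suspend) {
    if (suspended) # already suspended: clock keeps its original start
      return(list(state = state, action = act(rate = 0, note = "hold")))
    new <- state
    new$pre_suspension_rate <- state$infusion_rate
    new$infusion_rate <- 0
    new$suspended_since <- reading$t
    return(list(state = new, action = act(rate = 0, note = "suspend")))
  }

  if (state$boluses_given == 1L) {
    # one bolus, MBP recovered: nothing is infusing, nothing to titrate
    return(list(state = state, action = act(rate = 0, note = "hold")))
  }

  new_rate <- adjust_rate(running, mbp, r0, config)
  note <- if (suspended) "resume"
          else if (mbp < config$t_low) "step-up"
          else if (mbp < config$rate_policy$band_low) "hold"
          else "step-down"
  new <- state
  new$infusion_rate <- new_rate
  new$pre_suspension_rate <- 0
  new$suspended_since <- NA_real_
  list(state = new, action = act(rate = new_rate, note = note))
}

#' Replay the controller over a trajectory
#'
#' Folds [step_controller()] over a time-ordered sequence of NIBP readings,
#' emitting one dose action per reading.
#'
#' @param readings A list of [nibp_reading()] objects, or a trajectory
#'   data frame with columns `t_min, sbp, mbp, dbp, valid` (as read by
#'   [read_trajectory()]).
#' @param weight Body mass (kg).
#' @param config A [controller_config()].
#' @return List with `actions` (data frame: `t_min, bolus_mg, rate_mg_h,
#'   rate_ml_h, mode, note`) and `state` (final [controller_state()]).
#' @export
#' @examples
#' traj <- data.frame(t_min = c(0, 2.5, 5), sbp = c(95, 92, 110),
#'                    mbp = c(60, 58, 72), dbp = c(42, 41, 53), valid = 1)
#' run_controller(traj, weight = 70)$actions
run_controller <- function(readings, weight, config = controller_config()) {
  if (is.data.frame(readings)) readings <- trajectory_to_readings(readings)
  if (!length(readings))
    return(list(actions = empty_action_log(), state = controller_state()))
  times <- vapply(readings, `[[`, numeric(1), "t")
  if (is.unsorted(times, strictly = TRUE))
    stop("reading times must be strictly increasing", call. = FALSE)

  state <- controller_state()
  n <- length(readings)
  out <- data.frame(t_min = times, bolus_mg = numeric(n),
                    rate_mg_h = numeric(n), rate_ml_h = numeric(n),
                    mode = character(n), note = character(n))
  for (i in seq_len(n)) {
    res <- step_controller(state, readings[[i]], weight, config)
    state <- res$state
    out$bolus_mg[i] <- res$action$bolus
    out$rate_mg_h[i] <- res$action$rate_setpoint
    out$rate_ml_h[i] <- res$action$rate_setpoint / config$conc
    out$mode[i] <- state$mode
    out$note[i] <- res$action$note
  }
  list(actions = out, state = state)
}

empty_action_log <- function() {
  data.frame(t_min = numeric(0), bolus_mg = numeric(0),
             rate_mg_h = numeric(0), rate_ml_h = numeric(0),
             mode = character(0), note = character(0))
}

trajectory_to_readings <- function(df) {
  req <- c("t_min", "sbp", "mbp", "dbp", "valid")
  if (!all(req %in% names(df)))
    stop("trajectory needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    if (df$valid[i] %in% c(1, TRUE))
      nibp_reading(df$t_min[i], df$sbp[i], df$mbp[i], df$dbp[i], TRUE)
    else
      nibp_reading(df$t_min[i], valid = FALSE)
  })
}
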