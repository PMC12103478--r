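#' Classify NIBP epochs against the trial thresholds
#'
#' Each valid reading is labelled `ADEQUATE`, `HYPOTENSIVE` (MBP strictly
#' below `t_low`), `HYPERTENSIVE` (SBP strictly above `t_hyper`) or `BOTH`;
#' invalid readings are `MISSING` and excluded from every denominator
#' downstream. Boundary values (MBP exactly 65, SBP exactly 140) are
#' adequate.
#'
#' @param trajectory Data frame with columns `t_min, sbp, mbp, dbp, valid`,
#'   time-ordered.
#' @param t_low Hypotension threshold on MBP (mmHg). Default 65.
#' @param t_hyper Hypertension threshold on SBP (mmHg). Default 140.
#' @return Character vector of labels, one per reading.
#' @export
#' @examples
#' traj <- data.frame(t_min = c(0, 2.5), sbp = c(120, 150),
#'                    mbp = c(64, 90), dbp = c(50, 70), valid = 1)
#' classify_epochs(traj)
classify_epochs <- function(trajectory, t_low = 65, t_hyper = 140) {
  stopifnot(all(c("t_min", "sbp", "mbp", "valid") %in% names(trajectory)))
  if (is.unsorted(trajectory$t_min, strictly = TRUE))
    stop("readings must be time-ordered", call. = FALSE)
  valid <- trajectory$valid %in% c(1, TRUE)
  hypo <- valid & trajectory$mbp < t_low
  hyper <- valid & trajectory$sbp > t_hyper
  out <- rep("MISSING", nrow(trajectory))
  out[valid] <- "ADEQUATE"
  out[hypo & !hyper] <- "HYPOTENSIVE"
  out[hyper & !hypo] <- "HYPERTENSIVE"
  out[hypo & hyper] <- "BOTH"
  out
}

#' Endpoint percentages over the evaluation window
#'
#' Computes the per-patient endpoints as percentages of valid 2.5-min epochs:
#' hypotension time, hypertension time, and the adequate blood-pressure time
#' percentage, obtained by subtracting the percentage of epochs in the
#' *union* of hypotension and hypertension (epochs labelled `BOTH` count
#' once). `MISSING` epochs are excluded from the denominator.
#'
#' @param classifications Label vector from [classify_epochs()].
#' @param window Integer vector `c(first, last)` of reading indices bounding
#'   the evaluation period (inclusive). Default: all readings.
#' @return List with `adequate_pct`, `hypo_pct`, `hyper_pct` and `n_valid`.
#' @export
#' @examples
#' endpoint_percentages(c("ADEQUATE", "ADEQUATE", "HYPOTENSIVE", "ADEQUATE"))
endpoint_percentages <- function(classifications,
                                 window = c(1L, length(classifications))) {
  idx <- seq.int(window[1], window[2])
  lab <- classifications[idx]
  lab <- lab[lab != "MISSING"]
  if (!length(lab))
    stop("undefined endpoint: no valid epochs in the evaluation window",
         call. = FALSE)
  n <- length(lab)
  hypo <- lab %in% c("HYPOTENSIVE", "BOTH")
  hyper <- lab %in% c("HYPERTENSIVE", "BOTH")
  abnormal <- hypo | hyper
  list(adequate_pct = 100 - 100 * sum(abnormal) / n,
       hypo_pct = 100 * sum(hypo) / n,
       hyper_pct = 100 * sum(hyper) / n,
       n_valid = n)
}

#' Tabulate consecutive hypotensive episodes
#'
#' Decomposes the hypotensive indicator sequence into maximal runs and
#' counts them by length: single events, two / three consecutive events, and
#' four or more. `MISSING` epochs break runs (a run must be observed to be
#' consecutive). Run shares are returned both as exact fractions and as
#' round-half-up integer percentages.
#'
#' @param classifications Label vector from [classify_epochs()], or a
#'   0/1 hypotension indicator vector.
#' @return List with `counts` (named: `1`, `2`, `3`, `>=4`), `n_runs`,
#'   `total_hypotensive` (sum of run lengths), `share_pct` (exact, per
#'   category) and `share_pct_rounded` (round-half-up integers).
#' @export
#' @examples
#' tabulate_runs(c(1, 1, 0, 1, 0))
tabulate_runs <- function(classifications) {
  ind <- if (is.numeric(classifications) || is.logical(classifications)) {
    as.integer(classifications != 0)
  } else {
    ifelse(classifications == "MISSING", NA_integer_,
           as.integer(classifications %in% c("HYPOTENSIVE", "BOTH")))
  }
  ind[is.na(ind)] <- 0L # MISSING breaks runs
  r <- rle(ind)
  lens <- r$lengths[r$values == 1L]
  counts <- c(`1` = sum(lens == 1), `2` = sum(lens == 2),
              `3` = sum(lens == 3), `>=4` = sum(lens >= 4))
  n_runs <- sum(counts)
  share <- if (n_runs) 100 * counts / n_runs else counts * 0
  list(counts = counts, n_runs = n_runs,
       total_hypotensive = sum(lens),
       share_pct = share,
       share_pct_rounded = floor(share + 0.5))
}

#' Varvel performance-error indices
#'
#' Set-point control accuracy indices based on the percentage performance
#' error `PE_i = 100 * (measured_i - target) / target`:
#' \describe{
#'   \item{MDPE}{median performance error (bias, %).}
#'   \item{MDAPE}{median absolute performance error (inaccuracy, %).}
#'   \item{wobble}{median absolute deviation of PE from MDPE
#'     (intra-subject variability, %).}
#'   \item{divergence}{least-squares slope of |PE| against time
#'     (%/min; positive means control deteriorates over time).}
#' }
#' These indices presume target tracking; under lower-limit control two
#' trajectories with identical threshold compliance can have very different
#' MDPE/MDAPE, which is why threshold compliance is reported separately by
#' [lower_limit_compliance()].
#'
#' @param measured Measured values (e.g. MBP, mmHg), length >= 2.
#' @param target Positive reference value (mmHg).
#' @param times Measurement times (min), same length as `measured`.
#' @return List with `mdpe`, `mdape`, `wobble`, `divergence`.
#' @export
#' @examples
#' varvel_indices(c(63, 70, 77), target = 70, times = c(0, 2.5, 5))
varvel_indices <- function(measured, target, times) {
  if (length(measured) < 2)
    stop("need at least 2 readings", call. = FALSE)
  stopifnot(target > 0, length(times) == length(measured))
  pe <- 100 * (measured - target) / target
  mdpe <- stats::median(pe)
  mdape <- stats::median(abs(pe))
  wobble <- stats::median(abs(pe - mdpe))
  divergence <- unname(stats::coef(stats::lm(abs(pe) ~ times))[2])
  list(mdpe = mdpe, mdape = mdape, wobble = wobble, divergence = divergence)
}

#' Lower-limit compliance percentage
#'
#' The percentage of valid epochs meeting the lower-limit condition (not
#' hypotensive): `100 - hypo_pct`. This is the natural accuracy measure for
#' threshold control, where MDPE/MDAPE can rank trajectories perversely.
#'
#' @param classifications Label vector from [classify_epochs()].
#' @return Percentage in \\[0, 100\\].
#' @export
#' @examples
#' lower_limit_compliance(c("HYPOTENSIVE", "ADEQUATE", "ADEQUATE",
#'                          "ADEQUATE"))
lower_limit_compliance <- function(classifications) {
  lab <- classifications[classifications != "MISSING"]
  if (!length(lab))
    stop("undefined endpoint: no valid epochs", call. = FALSE)
  100 * sum(!lab %in% c("HYPOTENSIVE", "BOTH")) / length(lab)
}
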