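# Shared fixtures: random trajectories, label sequences, naive oracles.

# Random NIBP trajectory data frame on a 2.5-min grid. Pressures span the
# whole clinically interesting range so every controller branch is exercised.
random_trajectory <- function(n_epochs, invalid_prob = 0.1) {
  mbp <- runif(n_epochs, 40, 110)
  sbp <- mbp + runif(n_epochs, 15, 60)
  dbp <- pmax(mbp - runif(n_epochs, 10, 30), 1)
  data.frame(t_min = 2.5 * (seq_len(n_epochs) - 1),
             sbp = sbp, mbp = mbp, dbp = dbp,
             valid = as.integer(runif(n_epochs) >= invalid_prob))
}

# Random epoch-label sequence over the full alphabet.
random_labels <- function(n) {
  sample(c("ADEQUATE", "HYPOTENSIVE", "HYPERTENSIVE", "BOTH", "MISSING"),
         n, replace = TRUE, prob = c(0.5, 0.2, 0.1, 0.05, 0.15))
}

# Naive element-wise recount of endpoint percentages (independent of the
# vectorized implementation).
naive_percentages <- function(labels) {
  nv <- 0; hypo <- 0; hyper <- 0; abn <- 0
  for (l in labels) {
    if (l == "MISSING") next
    nv <- nv + 1
    is_hypo <- l == "HYPOTENSIVE" || l == "BOTH"
    is_hyper <- l == "HYPERTENSIVE" || l == "BOTH"
    if (is_hypo) hypo <- hypo + 1
    if (is_hyper) hyper <- hyper + 1
    if (is_hypo || is_hyper) abn <- abn + 1
  }
  if (nv == 0) return(NULL)
  list(adequate_pct = 100 - 100 * abn / nv, hypo_pct = 100 * hypo / nv,
       hyper_pct = 100 * hyper / nv, n_valid = nv)
}

# Naive run scan: walk the sequence accumulating maximal hypotensive runs,
# broken by anything that is not observed-hypotensive.
naive_runs <- function(labels) {
  counts <- c(`1` = 0, `2` = 0, `3` = 0, `>=4` = 0)
  total <- 0; cur <- 0
  flush <- function(cur, counts) {
    if (cur == 0) return(counts)
    key <- if (cur >= 4) ">=4" else as.character(cur)
    counts[key] <- counts[key] + 1
    counts
  }
  for (l in labels) {
    if (l == "HYPOTENSIVE" || l == "BOTH") {
      cur <- cur + 1; total <- total + 1
    } else {
      counts <- flush(cur, counts); cur <- 0
    }
  }
  counts <- flush(cur, counts)
  list(counts = counts, total = total)
}

# Independent recount of expected automated boluses from a trajectory.
# Tracks only the mode, bolus count and suspension clock — no rate
# titration — so it exercises a different code path from the controller.
expected_boluses <- function(traj, cfg = controller_config()) {
  mode <- "NORMAL"; boluses <- 0L; susp <- NA_real_
  entries <- 0L; seconds <- 0L
  for (i in seq_len(nrow(traj))) {
    if (traj$valid[i] == 0) next
    t <- traj$t_min[i]; mbp <- traj$mbp[i]
    if (mode == "VASOPRESSOR" && !is.na(susp) &&
        t - susp > cfg$exit_timeout) {
      mode <- "NORMAL"; boluses <- 0L; susp <- NA_real_
    }
    if (mode == "NORMAL") {
      if (mbp < cfg$t_low) {
        mode <- "VASOPRESSOR"; boluses <- 1L; entries <- entries + 1L
      }
    } else if (boluses == 1L && mbp < cfg$t_low) {
      seconds <- seconds + 1L; boluses <- 2L; susp <- NA_real_
    } else if (mbp > cfg$t_suspend) {
      if (is.na(susp)) susp <- t
    } else if (boluses == 2L) {
      susp <- NA_real_
    }
  }
  list(entries = entries, seconds = seconds)
}

# A raw sample with exactly the requested first two moments.
moment_matched_sample <- function(n, mean, sd) {
  x <- rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  mean + sd * x
}
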