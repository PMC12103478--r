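#' Read a trajectory CSV
#'
#' Schema: header `t_min, sbp, mbp, dbp, valid` with `valid` in \{0, 1\};
#' a leading `#`-comment line (schema version) is tolerated.
#'
#' @param path File path.
#' @return Data frame with the five columns, time-ordered.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  req <- c("t_min", "sbp", "mbp", "dbp", "valid")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("trajectory file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(df$valid %in% c(0, 1)))
    stop("trajectory 'valid' column must be 0/1 (", path, ")", call. = FALSE)
  bad <- which(df$valid == 1 &
                 (is.na(df$mbp) | df$mbp <= 0 | df$mbp >= 300))
  if (length(bad))
    stop("invalid pressure in ", path, " at row ", bad[1], call. = FALSE)
  if (is.unsorted(df$t_min, strictly = TRUE))
    stop("trajectory times must be strictly increasing (", path, ")",
         call. = FALSE)
  df[req]
}

#' Write a trajectory CSV
#' @param trajectory Data frame `t_min, sbp, mbp, dbp, valid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  writeLines("# pressorloop trajectory v1", path)
  suppressWarnings(utils::write.table(
    trajectory, path, sep = ",", row.names = FALSE, col.names = TRUE,
    append = TRUE, qmethod = "double"))
  invisible(path)
}

#' Write a controller action log CSV
#' @param actions Data frame `t_min, bolus_mg, rate_mg_h, rate_ml_h, mode,
#'   note` as produced by [run_controller()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_actions <- function(actions, path) {
  writeLines("# pressorloop actions v1", path)
  suppressWarnings(utils::write.table(
    actions, path, sep = ",", row.names = FALSE, col.names = TRUE,
    append = TRUE, qmethod = "double"))
  invisible(path)
}

#' Write a drug record as a per-epoch CSV
#'
#' Flattens a [drug_record()] onto a time grid: columns `t_min, bolus_mg,
#' rate_mg_h` (bolus given at that instant; rate in force from that instant).
#'
#' @param drug A [drug_record()].
#' @param times Time grid (min).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_record <- function(drug, times, path) {
  rate_at <- function(t) {
    s <- drug$infusion_segments
    hit <- which(s$start <= t & t < s$end)
    if (length(hit)) s$rate[hit[1]] else 0
  }
  bolus_at <- function(t) {
    b <- drug$boluses
    sum(b$dose[abs(b$t - t) < 1e-9])
  }
  df <- data.frame(t_min = times,
                   bolus_mg = vapply(times, bolus_at, numeric(1)),
                   rate_mg_h = vapply(times, rate_at, numeric(1)))
  writeLines("# pressorloop drug v1", path)
  suppressWarnings(utils::write.table(
    df, path, sep = ",", row.names = FALSE, col.names = TRUE,
    append = TRUE, qmethod = "double"))
  invisible(path)
}

#' Read a controller configuration from JSON
#'
#' The JSON mirrors [controller_config()] field names; absent fields take
#' their defaults.
#'
#' @param path JSON file path.
#' @return A [controller_config()].
#' @export
read_controller_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(controller_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown controller config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(controller_config, raw)
}

#' Write a controller configuration to JSON
#' @param config A [controller_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_controller_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
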