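#' Write a trial table to CSV
#'
#' RFC-4180 CSV, UTF-8, "." decimal. Columns as produced by
#' [simulate_session()] (plus any extra columns such as `t_star`, `rt`,
#' `error`).
#'
#' @param trials a data.frame of trials.
#' @param path output path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial file and split it into weighted cue streams
#'
#' Expects columns `trial`, `cue`, `category`, `signal`, `rt` and
#' optionally `error`. Rows flagged as errors get their reaction time set
#' to zero and a very low weight (default 1e-8), which effectively removes
#' them from the reaction-time likelihood without disturbing trial-to-trial
#' learning; all other rows get weight 1.
#'
#' @param path CSV file path.
#' @param units `"s"` (default) or `"ms"`; ms values are divided by 1000.
#' @param error_weight weight assigned to error trials.
#' @return a named list, one element per cue, each a data.frame with
#'   columns `trial`, `category`, `signal`, `rt`, `error`, `weight`, sorted
#'   by trial.
#' @export
read_trials <- function(path, units = c("s", "ms"), error_weight = 1e-8) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "cue", "signal", "rt")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("trial file is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$error)) df$error <- 0L
  if (is.null(df$category)) df$category <- NA_integer_
  bad <- which(!df$error %in% c(0L, 1L) |
                 (!is.na(df$rt) & df$rt < 0))
  if (length(bad)) {
    stop("malformed trial rows (rt < 0 or error not in {0,1}) at line(s): ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "))
  }
  if (units == "ms") df$rt <- df$rt / 1000
  df$weight <- ifelse(df$error == 1L, error_weight, 1)
  df$rt[df$error == 1L] <- 0
  streams <- split(df, df$cue)
  lapply(streams, function(s) {
    s <- s[order(s$trial), c("trial", "category", "signal", "rt", "error",
                             "weight")]
    rownames(s) <- NULL
    s
  })
}

#' Read a run configuration (YAML or JSON)
#'
#' Schema-checked configuration mirroring [schedule_config()],
#' [prior_spec()] and [inversion_config()]; unknown top-level keys are
#' rejected.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- c("model", "schedule", "perceptual", "response", "priors",
               "inversion", "seed", "units", "n_sims", "snr_db_levels",
               "series")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg
}
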