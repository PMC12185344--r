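trials_schema <- c("participant_id", "group", "arm", "phase", "day", "trial",
                   "p_win_left", "mag_win_left", "mag_loss_left",
                   "p_win_right", "mag_win_right", "mag_loss_right",
                   "choice", "outcome")
mood_schema <- c("participant_id", "group", "day", "panas_pos", "panas_neg",
                 "vas_pre", "vas_post")

check_schema <- function(df, schema, what) {
  miss <- setdiff(schema, names(df))
  extra <- setdiff(names(df), schema)
  if (length(miss)) {
    abort(paste0(what, " table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (length(extra)) {
    abort(paste0(what, " table has unexpected column(s): ",
                 paste(extra, collapse = ", ")))
  }
  df[, schema]
}

#' Validate a trial table
#'
#' Enforces the package's trial-table dialect: the exact column set, `choice`
#' coded `L`/`R`, probabilities as decimals in \[0, 1\], positive magnitudes,
#' and outcome integrity — each realized outcome must equal `+mag_win` or
#' `-mag_loss` of the chosen option, so the within-session previous-outcome
#' chain derived from outcomes is well defined.
#'
#' @param trials A data frame.
#' @return The validated tibble (columns in canonical order).
#' @export
validate_trials <- function(trials) {
  trials <- check_schema(as_tibble(trials), trials_schema, "Trials")
  if (!all(trials$choice %in% c("L", "R"))) {
    abort("`choice` must be coded 'L'/'R'.")
  }
  pr <- c(trials$p_win_left, trials$p_win_right)
  if (any(pr < 0 | pr > 1)) abort("Win probabilities must lie in [0, 1].")
  mags <- c(trials$mag_win_left, trials$mag_loss_left, trials$mag_win_right,
            trials$mag_loss_right)
  if (any(mags <= 0)) abort("Magnitudes must be positive points.")
  win <- ifelse(trials$choice == "L", trials$mag_win_left,
                trials$mag_win_right)
  loss <- ifelse(trials$choice == "L", trials$mag_loss_left,
                 trials$mag_loss_right)
  ok <- trials$outcome == win | trials$outcome == -loss
  if (!all(ok)) {
    abort("Outcome-chain integrity error: some realized outcomes match neither +mag_win nor -mag_loss of the chosen option.")
  }
  trials
}

#' Validate a mood table
#' @param mood A data frame.
#' @return The validated tibble.
#' @export
validate_mood <- function(mood) {
  mood <- check_schema(as_tibble(mood), mood_schema, "Mood")
  vas <- c(mood$vas_pre, mood$vas_post)
  if (any(vas < 0 | vas > 100, na.rm = TRUE)) {
    abort("Happiness VAS must lie in [0, 100].")
  }
  dup <- mood |> dplyr::count(.data$participant_id, .data$day) |>
    filter(.data$n > 1)
  if (nrow(dup)) abort("Duplicate participant-day rows in mood table.")
  mood
}

#' Read and write the package's CSV tables
#'
#' UTF-8 CSV with a header row, the fixed column dialect of
#' [validate_trials()] / [validate_mood()], and lossless round-tripping
#' (doubles are written with full precision).
#'
#' @param path File path.
#' @param trials,mood Tables to write.
#' @return Readers return validated tibbles; writers return the path,
#'   invisibly.
#' @name table_io
NULL

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

read_csv_plain <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8"))
}

#' @rdname table_io
#' @export
write_trials <- function(trials, path) {
  write_csv_plain(validate_trials(trials), path)
}

#' @rdname table_io
#' @export
read_trials <- function(path) validate_trials(read_csv_plain(path))

#' @rdname table_io
#' @export
write_mood <- function(mood, path) write_csv_plain(validate_mood(mood), path)

#' @rdname table_io
#' @export
read_mood <- function(path) validate_mood(read_csv_plain(path))
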