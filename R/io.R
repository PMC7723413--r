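trial_cols_required <- c("participant_id", "experiment", "frame", "block",
                         "trial_index", "r_left", "r_right", "dt_left_ms",
                         "dt_right_ms", "rt_s", "choice", "confidence")

#' Read and write trial tables
#'
#' The trial table is a CSV/TSV with one row per trial and columns
#' `participant_id`, `experiment` (value|perceptual), `frame`
#' (like|dislike|most|fewest), `block`, `trial_index`, `r_left`, `r_right`,
#' `dt_left_ms`, `dt_right_ms`, `rt_s`, `choice` (left|right), `confidence`,
#' and optionally `gsf` and further design columns. Validation reports the
#' first offending row of each violated rule.
#'
#' @param path File path (`.tsv` files are read/written tab-separated).
#' @return A validated trial tibble.
#' @export
read_trials <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  d <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_trials(d)
}

#' @rdname read_trials
#' @param data Trial tibble.
#' @export
write_trials <- function(data, path) {
  validate_trials(data)
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(data, path, progress = FALSE)
  invisible(path)
}

#' Validate a trial table
#'
#' @param data Trial tibble.
#' @return The tibble, invisibly usable in a pipe; errors name the first
#'   offending row.
#' @export
validate_trials <- function(data) {
  missing_cols <- setdiff(trial_cols_required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  fail_row <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf("%s (first offending row: %d)", what, which(!ok)[1]))
    }
  }
  fail_row(data$experiment %in% c("value", "perceptual"),
           "experiment must be 'value' or 'perceptual'")
  fail_row(data$frame %in% glam_frames, "invalid frame")
  fail_row(data$choice %in% c("left", "right"),
           "choice must be 'left' or 'right'")
  fail_row(data$rt_s > 0, "rt_s must be positive")
  fail_row(data$dt_left_ms >= 0 & data$dt_right_ms >= 0,
           "dwell times must be non-negative")
  fail_row(data$dt_left_ms + data$dt_right_ms <= data$rt_s * 1000 + 1e-6,
           "dwell times exceed the response time")
  vf <- data$frame %in% c("like", "dislike")
  fail_row(ifelse(vf, data$r_left >= 0 & data$r_left <= 3 &
                        data$r_right >= 0 & data$r_right <= 3,
                  data$r_left >= 40 & data$r_left <= 133 &
                    data$r_right >= 40 & data$r_right <= 133),
           "evidence outside the experiment's scale")
  one_exp <- tapply(data$experiment, data$participant_id,
                    function(x) length(unique(x)) == 1L)
  if (!all(one_exp)) {
    stop("participant(s) mixing experiments: ",
         paste(names(one_exp)[!one_exp], collapse = ", "))
  }
  data
}

#' Read and write fixation tables
#'
#' Long-format companion to the trial table: `participant_id`,
#' `trial_index`, `fix_index`, `side` (left|right), `onset_ms`,
#' `duration_ms`, with strictly increasing onsets within a trial.
#'
#' @param path File path.
#' @return A validated fixation tibble.
#' @export
read_fixations <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  d <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_fixations(d)
}

#' @rdname read_fixations
#' @param data Fixation tibble.
#' @export
write_fixations <- function(data, path) {
  validate_fixations(data)
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(data, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_fixations
#' @export
validate_fixations <- function(data) {
  req <- c("participant_id", "trial_index", "fix_index", "side", "onset_ms",
           "duration_ms")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(data$side %in% c("left", "right"))) {
    stop("fixation side must be 'left' or 'right' (first offending row: ",
         which(!data$side %in% c("left", "right"))[1], ")")
  }
  if (any(data$duration_ms <= 0)) {
    stop("fixation durations must be positive (first offending row: ",
         which(data$duration_ms <= 0)[1], ")")
  }
  ok <- unlist(lapply(split(seq_len(nrow(data)),
                            paste(data$participant_id, data$trial_index)),
                      function(idx) {
    o <- data$onset_ms[idx][order(data$fix_index[idx])]
    c(TRUE, diff(o) > 0)
  }))
  if (!all(ok)) stop("fixation onsets must be strictly increasing within a trial")
  data
}
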