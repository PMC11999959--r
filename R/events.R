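# Cue event tables (CSV) and generator ground truth (JSON).

EVENT_COLUMNS <- c("onset_s", "type", "target_char", "trial_idx", "condition")

validate_events <- function(events) {
  missing <- setdiff(setdiff(EVENT_COLUMNS, "condition"), names(events))
  if (length(missing) > 0) {
    abort(sprintf("event table is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!all(events$type %in% c("column", "row"))) {
    abort("event `type` must be 'column' or 'row'")
  }
  if (anyDuplicated(events[, c("trial_idx", "type")])) {
    abort("duplicate trial_idx with the same event type")
  }
  invisible(events)
}

#' Read / write a cue event table
#'
#' Event tables hold one row per column/row cue with columns `onset_s`,
#' `type`, `target_char`, `trial_idx`, `condition`. Reading sorts events by
#' onset and enforces integrity (no duplicated trial index within an event
#' type).
#'
#' @param path CSV file path.
#' @return `read_events()`: a sorted event tibble.
#' @export
read_events <- function(path) {
  # trim_ws = FALSE: the space character is a legitimate speller target
  events <- readr::read_csv(path, trim_ws = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
  validate_events(events)
  events$onset_s <- as.numeric(events$onset_s)
  events$trial_idx <- as.integer(events$trial_idx)
  if (anyNA(events$onset_s) || anyNA(events$trial_idx)) {
    abort("non-numeric `onset_s`/`trial_idx` in event table")
  }
  dplyr::arrange(events, .data$onset_s)
}

#' @rdname read_events
#' @param events Event tibble as produced by [simulate_session()].
#' @export
write_events <- function(events, path) {
  validate_events(events)
  readr::write_csv(events, path)
  invisible(path)
}

#' Read / write generator ground truth
#'
#' Ground truth records, per trial, whether an MRCP was planted and the
#' planted PN time and EMG onset (absolute seconds), plus the success
#' probability used for the subject.
#'
#' @param truth Ground-truth tibble from [synth_subject()].
#' @param path JSON file path.
#' @return `read_ground_truth()`: the ground-truth tibble with
#'   `success_prob` and `seed` attributes restored.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(
    success_prob = attr(truth, "success_prob"),
    seed = attr(truth, "seed"),
    trials = truth
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- tibble::as_tibble(payload$trials)
  truth$trial_idx <- as.integer(truth$trial_idx)
  attr(truth, "success_prob") <- payload$success_prob
  attr(truth, "seed") <- payload$seed
  truth
}
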