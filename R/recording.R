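# Continuous multichannel recordings and epoch sets (lightweight S3 records).

#' Construct a continuous recording
#'
#' @param data Numeric matrix, samples in rows and channels in columns, in uV.
#' @param rate Sampling rate in Hz.
#' @param labels Channel labels; defaults to `colnames(data)`.
#' @param start_time Time of the first sample in seconds. Default 0.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, rate, labels = colnames(data), start_time = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data)) abort("`data` must be numeric with no missing samples")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) abort("`rate` must be a positive scalar")
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(data)))
  if (length(labels) != ncol(data)) abort("one label per channel is required")
  if (anyDuplicated(labels)) abort("channel labels must be unique")
  colnames(data) <- labels
  structure(
    list(data = data, rate = rate, labels = labels, start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    ncol(x$data), nrow(x$data), x$rate, nrow(x$data) / x$rate
  ))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / duration helpers
#' @param x An `eeg_recording`.
#' @return `n_samples()`: integer; `duration()`: seconds.
#' @export
n_samples <- function(x) nrow(x$data)

#' @rdname n_samples
#' @export
duration <- function(x) nrow(x$data) / x$rate

new_epoch_set <- function(data, time_s, rate, reference, trial_idx,
                          channel = NA_character_, condition = NA_character_,
                          subject = NA_character_) {
  stopifnot(is.matrix(data), length(time_s) == ncol(data),
            length(trial_idx) == nrow(data))
  structure(
    list(data = data, time_s = time_s, rate = rate, reference = reference,
         trial_idx = as.integer(trial_idx), channel = channel,
         condition = condition, subject = subject),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d trial(s) x %d samples @ %g Hz, t in [%.3f, %.3f] s (reference: %s)\n",
    nrow(x$data), ncol(x$data), x$rate, min(x$time_s), max(x$time_s), x$reference
  ))
  invisible(x)
}

#' Convert an epoch set to a long tibble
#'
#' @param x An `epoch_set`.
#' @param ... Unused.
#' @return Tibble with columns `trial_idx`, `time_s`, `value_uv` plus the
#'   epoch set's `channel`, `condition`, `subject` identifiers.
#' @method as_tibble epoch_set
#' @export
as_tibble.epoch_set <- function(x, ...) {
  tibble::tibble(
    trial_idx = rep(x$trial_idx, each = length(x$time_s)),
    time_s = rep(x$time_s, times = nrow(x$data)),
    value_uv = as.vector(t(x$data)),
    channel = x$channel,
    condition = x$condition,
    subject = x$subject
  )
}

#' Per-timepoint mean trace of an epoch set
#'
#' @param x An `epoch_set`.
#' @return Tibble with `time_s`, `value_uv` (mean across trials), `n_trials`,
#'   and the set's identifiers.
#' @export
epoch_mean <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  tibble::tibble(
    time_s = x$time_s,
    value_uv = colMeans(x$data),
    n_trials = nrow(x$data),
    channel = x$channel,
    condition = x$condition,
    subject = x$subject
  )
}
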