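# Filtering, epoching, demeaning, large Laplacian.

#' Butterworth filter specification
#'
#' The preprocessing chain uses two 2nd-order Butterworth filters: a 50 Hz
#' notch realized as a band-stop over 48-52 Hz, and a 0.05-3 Hz band-pass.
#' Filters are applied zero-phase (forward-backward) by default, which doubles
#' the effective order and removes group delay; causal application is
#' available via `zero_phase = FALSE`.
#'
#' @param kind `"notch"` (band-stop) or `"bandpass"`.
#' @param band Length-2 Hz pair; defaults 48-52 for the notch, 0.05-3 for the
#'   band-pass.
#' @param order Butterworth prototype order. Default 2.
#' @param zero_phase Apply forward-backward? Default `TRUE`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "notch"), band = NULL, order = 2,
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (is.null(band)) band <- if (kind == "notch") c(48, 52) else c(0.05, 3)
  if (length(band) != 2 || !(band[1] > 0) || !(band[2] > band[1])) {
    abort("`band` must satisfy 0 < low < high")
  }
  structure(
    list(kind = kind, band = band, order = order, zero_phase = zero_phase),
    class = "filter_spec"
  )
}

#' The study's default filter chain (notch, then band-pass)
#' @return List of two [filter_spec()] objects.
#' @export
default_filters <- function() {
  list(filter_spec("notch"), filter_spec("bandpass"))
}

#' Apply a Butterworth filter to every channel of a recording
#'
#' @param rec An [recording()].
#' @param spec A [filter_spec()], or a list of them applied in order.
#' @return Filtered [recording()] of the same shape and rate.
#' @export
apply_filter <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.list(spec) && !inherits(spec, "filter_spec")) {
    for (s in spec) rec <- apply_filter(rec, s)
    return(rec)
  }
  if (spec$band[2] >= rec$rate / 2) {
    abort(sprintf("filter band [%g, %g] Hz exceeds the Nyquist frequency %g Hz",
                  spec$band[1], spec$band[2], rec$rate / 2))
  }
  w <- spec$band / (rec$rate / 2)
  bf <- signal::butter(spec$order, w,
                       type = if (spec$kind == "notch") "stop" else "pass")
  out <- rec$data
  for (ch in seq_len(ncol(out))) {
    out[, ch] <- if (spec$zero_phase) {
      signal::filtfilt(bf, rec$data[, ch])
    } else {
      as.numeric(signal::filter(bf, rec$data[, ch]))
    }
  }
  recording(out, rate = rec$rate, labels = rec$labels,
            start_time = rec$start_time)
}

#' Segment a recording channel into cue-aligned epochs
#'
#' Cuts one epoch per event with a half-open sample window
#' `[onset + window[1], onset + window[2])`; time 0 is the event onset. At
#' 1,200 Hz the default -4 to +5 s window gives 10,800 samples per epoch.
#'
#' @param rec An [recording()].
#' @param events Event tibble (see [simulate_session()]).
#' @param channel Channel label to extract; defaults to the first channel.
#' @param window Length-2 window in seconds relative to onset. Default
#'   `c(-4, 5)`.
#' @return An `epoch_set` with `reference = "cue"`.
#' @export
segment_epochs <- function(rec, events, channel = rec$labels[1],
                           window = c(-4, 5)) {
  stopifnot(inherits(rec, "eeg_recording"))
  validate_events(events)
  if (!channel %in% rec$labels) {
    abort(sprintf("channel '%s' not present in recording", channel))
  }
  n_samp <- round((window[2] - window[1]) * rec$rate)
  x <- rec$data[, channel]
  i0 <- round((events$onset_s - rec$start_time) * rec$rate) + 1L
  starts <- i0 + round(window[1] * rec$rate)
  bad <- starts < 1L | (starts + n_samp - 1L) > length(x)
  if (any(bad)) {
    abort(sprintf(
      "epoch window outside recording for trial(s): %s",
      paste(events$trial_idx[bad], collapse = ", ")
    ))
  }
  data <- t(vapply(starts, function(s) x[s:(s + n_samp - 1L)], numeric(n_samp)))
  time_s <- window[1] + (seq_len(n_samp) - 1L) / rec$rate
  cond <- if ("condition" %in% names(events)) events$condition[1] else NA_character_
  new_epoch_set(data, time_s, rec$rate, reference = "cue",
                trial_idx = events$trial_idx, channel = channel,
                condition = cond)
}

#' Remove each epoch's mean (offset correction)
#'
#' @param epochs An `epoch_set`.
#' @return The epoch set with per-trial means subtracted (idempotent).
#' @export
demean_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$data <- epochs$data - rowMeans(epochs$data)
  epochs
}

#' Large Laplacian spatial filter
#'
#' Subtracts the mean of the next-nearest-neighbor ring from the center
#' electrode, sample-wise: `out = center - mean(ring)`.
#'
#' @param rec An [recording()] containing all required channels.
#' @param center Center electrode. Default `"Cz"`.
#' @param ring Ring electrodes. Default `c("Fz", "C3", "C4", "Pz")`.
#' @return Single-channel [recording()] labelled `"<center>_lap"`.
#' @export
large_laplacian <- function(rec, center = "Cz",
                            ring = c("Fz", "C3", "C4", "Pz")) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(c(center, ring), rec$labels)
  if (length(missing) > 0) {
    abort(sprintf("missing channel label(s): %s", paste(missing, collapse = ", ")))
  }
  out <- rec$data[, center] - rowMeans(rec$data[, ring, drop = FALSE])
  recording(matrix(out, ncol = 1), rate = rec$rate,
            labels = paste0(center, "_lap"), start_time = rec$start_time)
}
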