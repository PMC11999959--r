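# EMG movement-onset detection: envelope, baseline threshold, morphological
# closing/opening, minimum-duration rule.

#' EMG onset detection parameters
#'
#' @param hp_cutoff High-pass cutoff for the envelope pre-filter, Hz.
#'   Default 20.
#' @param lp_cutoff Low-pass cutoff after full-wave rectification, Hz.
#'   Default 5.
#' @param k_threshold Threshold in baseline SDs above the baseline mean.
#'   Default 3.
#' @param struct_len_s Structuring-element length for morphological closing
#'   and opening, s. Default 0.05.
#' @param min_burst_s Minimum accepted supra-threshold run, s. Default 1.5
#'   (movement sustained for about 2 s).
#' @param baseline_window Interval relative to the trial reference used as
#'   baseline, s. Default `c(-1.5, -0.5)`: in the scanning paradigm
#'   consecutive selections can be as little as 4 s apart, so an earlier
#'   baseline can fall on the previous trial's burst; this window is the
#'   latest quiet interval that still clears the upcoming movement.
#' @return An object of class `emg_onset_params`.
#' @export
emg_onset_params <- function(hp_cutoff = 20, lp_cutoff = 5, k_threshold = 3,
                             struct_len_s = 0.05, min_burst_s = 1.5,
                             baseline_window = c(-1.5, -0.5)) {
  stopifnot(hp_cutoff > 0, lp_cutoff > 0, k_threshold > 0, struct_len_s > 0,
            min_burst_s > 0)
  if (!(baseline_window[1] < baseline_window[2] && baseline_window[2] <= 0)) {
    abort("`baseline_window` must precede the cue")
  }
  structure(
    list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
         k_threshold = k_threshold, struct_len_s = struct_len_s,
         min_burst_s = min_burst_s, baseline_window = baseline_window),
    class = "emg_onset_params"
  )
}

#' EMG amplitude envelope
#'
#' High-pass, full-wave rectification, low-pass (all zero-phase); the output
#' is clamped at zero so the envelope is non-negative.
#'
#' @param x Numeric EMG trace (one epoch).
#' @param rate Sampling rate, Hz.
#' @param params An [emg_onset_params()].
#' @return Non-negative envelope, same length as `x`.
#' @export
emg_envelope <- function(x, rate, params = emg_onset_params()) {
  if (params$hp_cutoff >= rate / 2 || params$lp_cutoff >= rate / 2) {
    abort("envelope cutoffs must be below the Nyquist frequency")
  }
  hp <- signal::butter(2, params$hp_cutoff / (rate / 2), type = "high")
  lp <- signal::butter(2, params$lp_cutoff / (rate / 2), type = "low")
  env <- signal::filtfilt(lp, abs(signal::filtfilt(hp, x)))
  pmax(env, 0)
}

#' Morphological closing / opening of a binary sequence
#'
#' With a structuring element of length `len` samples, closing bridges
#' interior sub-threshold (FALSE) gaps shorter than `len`, and opening removes
#' supra-threshold (TRUE) blips shorter than `len`.
#'
#' @param b Logical vector.
#' @param len Structuring-element length in samples.
#' @return Logical vector of the same length.
#' @export
morph_close <- function(b, len) {
  r <- rle(b)
  n <- length(r$values)
  interior <- seq_len(n) > 1 & seq_len(n) < n
  r$values[!r$values & interior & r$lengths < len] <- TRUE
  inverse.rle(r)
}

#' @rdname morph_close
#' @export
morph_open <- function(b, len) {
  r <- rle(b)
  r$values[r$values & r$lengths < len] <- FALSE
  inverse.rle(r)
}

# single-trace onset: returns time (s, epoch reference) or NA
detect_onset_trace <- function(x, time_s, rate, params) {
  bl <- time_s >= params$baseline_window[1] & time_s < params$baseline_window[2]
  if (!any(bl)) abort("baseline window is empty")
  env <- emg_envelope(x, rate, params)
  thr <- mean(env[bl]) + params$k_threshold * sd(env[bl])
  b <- env > thr
  L <- max(1L, round(params$struct_len_s * rate))
  b <- morph_open(morph_close(b, L), L)
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # runs beginning before the baseline window ends belong to a preceding
  # selection (consecutive movements can be only 4 s apart in this paradigm)
  ok <- r$values & r$lengths >= round(params$min_burst_s * rate) &
    time_s[starts] >= params$baseline_window[2]
  if (!any(ok)) return(NA_real_)
  time_s[starts[which(ok)[1]]]
}

#' Detect movement onset in EMG epochs
#'
#' Binarizes the envelope at `baseline mean + k * baseline SD` (baseline taken
#' from `baseline_window` relative to the cue), applies morphological closing
#' then opening, and reports the first sample of the first supra-threshold run
#' lasting at least `min_burst_s`. The threshold is baseline-relative, so the
#' estimate is invariant to overall EMG gain.
#'
#' @param epochs An `epoch_set` of the EMG channel (cue-aligned).
#' @param params An [emg_onset_params()].
#' @return Tibble with `trial_idx` and `emg_onset_s` (NA when no qualifying
#'   burst).
#' @export
detect_emg_onset <- function(epochs, params = emg_onset_params()) {
  stopifnot(inherits(epochs, "epoch_set"))
  onsets <- vapply(seq_len(nrow(epochs$data)), function(i) {
    detect_onset_trace(epochs$data[i, ], epochs$time_s, epochs$rate, params)
  }, numeric(1))
  tibble::tibble(trial_idx = epochs$trial_idx, emg_onset_s = onsets)
}
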