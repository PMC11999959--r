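# MRCP waveform template and synthetic-noise parameter records.

#' MRCP template parameters
#'
#' The planted MRCP is piecewise linear relative to its peak negativity (PN)
#' at time 0: flat at baseline until `ns1_start_s` before PN, then the shallow
#' early negative slope (NS1), then the steeper late negative slope (NS2) from
#' `ns2_start_s` before PN down to the PN, then a positive rebound back to
#' baseline. The PN depth is determined by the slope geometry:
#' `pn_amplitude = ns1_slope * (ns1_start_s - ns2_start_s) + ns2_slope * ns2_start_s`
#' (defaults close to -8 uV). Corners are optionally smoothed by convolution
#' with a Hann kernel of width `smoothing_s`.
#'
#' @param ns1_slope Early negative slope, uV/s (< 0). Default -2.
#' @param ns2_slope Late negative slope, uV/s (< `ns1_slope`). Default -10.
#' @param rebound_slope Post-PN positive slope, uV/s (> 0). Default +8.
#' @param ns1_start_s Time before PN at which the negativity begins. Default 2.
#' @param ns2_start_s Time before PN at which the steeper slope begins.
#'   Default 0.5.
#' @param smoothing_s Corner-smoothing kernel width in seconds (0 disables).
#'   Default 0.1.
#' @return An object of class `mrcp_template_params`; the derived field
#'   `pn_amplitude` (uV) is included.
#' @export
mrcp_template_params <- function(ns1_slope = -2, ns2_slope = -10,
                                 rebound_slope = 8, ns1_start_s = 2,
                                 ns2_start_s = 0.5, smoothing_s = 0.1) {
  if (!(ns1_slope < 0)) abort("`ns1_slope` must be negative")
  if (!(ns2_slope < ns1_slope)) abort("`ns2_slope` must be steeper (more negative) than `ns1_slope`")
  if (!(rebound_slope > 0)) abort("`rebound_slope` must be positive")
  if (!(ns1_start_s > ns2_start_s && ns2_start_s > 0)) {
    abort("need `ns1_start_s` > `ns2_start_s` > 0")
  }
  if (smoothing_s < 0) abort("`smoothing_s` must be non-negative")
  pn <- ns1_slope * (ns1_start_s - ns2_start_s) + ns2_slope * ns2_start_s
  structure(
    list(ns1_slope = ns1_slope, ns2_slope = ns2_slope,
         rebound_slope = rebound_slope, ns1_start_s = ns1_start_s,
         ns2_start_s = ns2_start_s, smoothing_s = smoothing_s,
         pn_amplitude = pn),
    class = "mrcp_template_params"
  )
}

#' Synthetic noise and jitter parameters
#'
#' Amplitudes of the synthetic background: 1/f ("pink") EEG noise, 50 Hz line
#' interference, sub-0.05 Hz drift, the EMG baseline carrier and burst gain,
#' and the timing jitters of the planted EMG onset and peak negativity around
#' the expected movement time (cue + midpoint offset).
#'
#' The defaults emulate a clean laboratory recording in which planted MRCPs
#' remain decidable by the per-trial criteria: broadband pink SD 1.5 uV leaves
#' roughly 1.4 uV of in-band (0.05-3 Hz) background against an 8 uV peak
#' negativity.
#'
#' @param pink_sigma Broadband SD of the 1/f EEG background, uV. Default 1.5.
#' @param line_amp 50 Hz line amplitude, uV. Default 5.
#' @param drift_amp Slow (< 0.05 Hz) drift amplitude, uV. Default 10.
#' @param emg_baseline_sigma EMG baseline noise SD, uV. Default 10.
#' @param emg_burst_gain Multiplicative burst amplitude. Default 10.
#' @param emg_onset_jitter_s SD of the EMG onset around the expected movement
#'   time, s. Default 0.1.
#' @param pn_jitter_s SD of the PN around the expected movement time, s.
#'   Default 0.15.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(pink_sigma = 1.5, line_amp = 5, drift_amp = 10,
                         emg_baseline_sigma = 10, emg_burst_gain = 10,
                         emg_onset_jitter_s = 0.1, pn_jitter_s = 0.15) {
  vals <- c(pink_sigma, line_amp, drift_amp, emg_baseline_sigma,
            emg_burst_gain, emg_onset_jitter_s, pn_jitter_s)
  if (any(vals < 0)) abort("all noise parameters must be non-negative")
  structure(
    list(pink_sigma = pink_sigma, line_amp = line_amp, drift_amp = drift_amp,
         emg_baseline_sigma = emg_baseline_sigma,
         emg_burst_gain = emg_burst_gain,
         emg_onset_jitter_s = emg_onset_jitter_s, pn_jitter_s = pn_jitter_s),
    class = "noise_params"
  )
}

#' Noise-free study conditions
#'
#' Zeroes the EEG background (pink, line, drift) and both timing jitters while
#' keeping the EMG baseline carrier: the EMG burst is modelled as
#' gain-modulated baseline activity, so a silent EMG channel would carry no
#' detectable movement at all. Used for exact parameter-recovery checks.
#'
#' @return A [noise_params()] object.
#' @export
noise_params_off <- function() {
  noise_params(pink_sigma = 0, line_amp = 0, drift_amp = 0,
               emg_onset_jitter_s = 0, pn_jitter_s = 0)
}

#' Evaluate the MRCP template on a time axis
#'
#' @param time_s Numeric time axis in seconds relative to the peak negativity
#'   (PN at 0). Must cover at least `[-ns1_start_s, 1.5]` and be uniformly
#'   spaced when `smoothing_s > 0`.
#' @param params A [mrcp_template_params()].
#' @return Waveform in uV, same length as `time_s`.
#' @examples
#' tt <- seq(-3, 2, by = 1 / 1200)
#' w <- mrcp_template(tt, mrcp_template_params(smoothing_s = 0))
#' min(w) # the PN amplitude, -8
#' @export
mrcp_template <- function(time_s, params = mrcp_template_params()) {
  if (min(time_s) > -params$ns1_start_s || max(time_s) < 1.5) {
    abort("time axis too short: must cover [-ns1_start_s, 1.5] s around the PN")
  }
  v2 <- params$ns1_slope * (params$ns1_start_s - params$ns2_start_s)
  t_end <- -params$pn_amplitude / params$rebound_slope
  knots_t <- c(-params$ns1_start_s, -params$ns2_start_s, 0, t_end)
  knots_v <- c(0, v2, params$pn_amplitude, 0)
  w <- approx(knots_t, knots_v, xout = time_s, rule = 2)$y
  if (params$smoothing_s > 0) {
    dt <- diff(time_s)
    if (max(dt) - min(dt) > 1e-9 * mean(dt)) {
      abort("`time_s` must be uniformly spaced when smoothing is enabled")
    }
    w <- smooth_hann(w, width = params$smoothing_s, dt = mean(dt))
  }
  w
}

# Zero-phase Hann smoothing with edge replication; kernel length forced odd.
smooth_hann <- function(x, width, dt) {
  L <- max(3L, round(width / dt))
  if (L %% 2 == 0) L <- L + 1L
  h <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  h <- h / sum(h)
  half <- (L - 1L) / 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, h, sides = 2))[(half + 1L):(half + length(x))]
}
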