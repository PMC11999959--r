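# Ground-truthed synthetic EEG + EMG realizing a session plan.

# channels that flank Cz and receive half of the planted waveform; the outer
# frontal/parietal sites receive a quarter (keeps the large Laplacian
# nontrivial: it shrinks but does not cancel the planted signal)
NEAR_RING <- c("FC1", "FC2", "C3", "C4", "CP1", "CP2")
FAR_RING <- c("FP1", "Fz", "Pz")

# 1/f-amplitude noise via spectral shaping; sd normalized per realization
pink_noise <- function(n, sigma) {
  if (sigma == 0) return(numeric(n))
  nf <- n %/% 2 + 1
  amp <- c(0, 1 / sqrt(seq_len(nf - 1)))
  phase <- runif(nf) * 2 * pi
  spec <- amp * exp(1i * phase)
  spec[1] <- 0
  if (n %% 2 == 0) spec[nf] <- Re(spec[nf])
  mirror <- if (n %% 2 == 0) Conj(spec[(nf - 1):2]) else Conj(spec[nf:2])
  full <- c(spec, mirror)
  x <- Re(fft(full, inverse = TRUE))
  x / sd(x) * sigma
}

raised_cosine_ramp <- function(n) {
  if (n <= 0) return(numeric(0))
  0.5 - 0.5 * cos(pi * seq_len(n) / n)
}

#' Synthesize one subject-condition recording
#'
#' Generates 1,200 Hz (by default) EEG and EMG spanning a whole session. For
#' each cue in `plan`, with probability `success_prob` an MRCP template is
#' added to Cz (with attenuated copies on the neighboring channels: factor
#' `spread_near` on the ring around Cz, `spread_far` on the outer
#' frontal/parietal sites) with its peak negativity jittered around the
#' expected movement time (cue onset + midpoint offset), and a 2-s EMG burst
#' (gain-modulated baseline noise with a 50 ms raised-cosine onset ramp) is
#' added to the tibialis-anterior channel. Remaining trials receive noise
#' only. Every planted time is recorded in the returned ground truth.
#'
#' @param plan Event tibble from [simulate_session()].
#' @param template A [mrcp_template_params()].
#' @param noise A [noise_params()].
#' @param success_prob Probability that a trial carries a planted MRCP + EMG
#'   burst, in `[0, 1]`.
#' @param seed Integer seed (required; generation is bit-reproducible).
#' @param timing The [timing_spec()] used to build `plan` (for the midpoint
#'   offset).
#' @param rate Sampling rate in Hz. Default 1200.
#' @param tail_s Quiet seconds appended after the last cue. Default 6.
#' @param spread_near,spread_far Fractions of the Cz waveform planted on the
#'   neighboring and outer channels. Defaults 0.5 and 0.25.
#' @param burst_duration_s EMG burst duration (sustained movement). Default 2.
#' @return A list of class `mrcp_subject` with elements `eeg`
#'   (10-channel [recording()]), `emg` (single-channel [recording()]),
#'   `events` (the plan), `truth` (ground-truth tibble with per-trial
#'   `mrcp_present`, `true_pn_time_s`, `true_emg_onset_s`).
#' @export
synth_subject <- function(plan, template = mrcp_template_params(),
                          noise = noise_params(), success_prob, seed,
                          timing = timing_spec(), rate = 1200, tail_s = 6,
                          spread_near = 0.5, spread_far = 0.25,
                          burst_duration_s = 2) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  if (!is.numeric(success_prob) || success_prob < 0 || success_prob > 1) {
    abort("`success_prob` must lie in [0, 1]")
  }
  validate_events(plan)
  n_sec <- ceiling(max(plan$onset_s) + tail_s)
  n <- n_sec * rate
  tt <- seq(0, length.out = n, by = 1 / rate)
  nt <- nrow(plan)

  withr::with_seed(seed, {
    # --- EEG background ---
    eeg <- matrix(0, n, length(EEG_CHANNELS))
    colnames(eeg) <- EEG_CHANNELS
    for (ch in seq_along(EEG_CHANNELS)) {
      x <- pink_noise(n, noise$pink_sigma)
      if (noise$line_amp > 0) {
        x <- x + noise$line_amp * sin(2 * pi * 50 * tt + runif(1) * 2 * pi)
      }
      if (noise$drift_amp > 0) {
        f0 <- runif(1, 0.01, 0.04)
        x <- x + noise$drift_amp * sin(2 * pi * f0 * tt + runif(1) * 2 * pi)
      }
      eeg[, ch] <- x
    }

    # --- trial assignment and planted times ---
    present <- if (success_prob >= 1) rep(TRUE, nt) else runif(nt) < success_prob
    pn_jit <- rnorm(nt, 0, noise$pn_jitter_s)
    emg_jit <- rnorm(nt, 0, noise$emg_onset_jitter_s)
    pn_times <- plan$onset_s + timing$midpoint_offset_s + pn_jit
    emg_onsets <- plan$onset_s + timing$midpoint_offset_s + emg_jit

    # --- plant MRCPs ---
    gain <- stats::setNames(rep(0, length(EEG_CHANNELS)), EEG_CHANNELS)
    gain["Cz"] <- 1
    gain[NEAR_RING] <- spread_near
    gain[FAR_RING] <- spread_far
    t_end <- -template$pn_amplitude / template$rebound_slope
    pad <- 4 * template$smoothing_s + 1 / rate
    for (i in which(present)) {
      lo <- max(1L, floor((pn_times[i] - template$ns1_start_s - pad) * rate) + 1L)
      hi <- min(n, ceiling((pn_times[i] + max(t_end, 1.5) + pad) * rate) + 1L)
      idx <- lo:hi
      w <- mrcp_template(tt[idx] - pn_times[i], template)
      for (ch in seq_along(EEG_CHANNELS)) {
        if (gain[ch] > 0) eeg[idx, ch] <- eeg[idx, ch] + gain[ch] * w
      }
    }

    # --- EMG ---
    emg <- rnorm(n, 0, noise$emg_baseline_sigma)
    ramp_n <- round(0.05 * rate)
    for (i in which(present)) {
      i0 <- round(emg_onsets[i] * rate) + 1L
      i1 <- min(n, i0 + round(burst_duration_s * rate) - 1L)
      if (i0 < 1L || i0 > n) next
      len <- i1 - i0 + 1L
      env <- rep(1, len)
      nr <- min(ramp_n, len)
      env[seq_len(nr)] <- raised_cosine_ramp(nr)
      emg[i0:i1] <- emg[i0:i1] * (1 + (noise$emg_burst_gain - 1) * env)
    }
  })

  truth <- tibble::tibble(
    trial_idx = plan$trial_idx,
    onset_s = plan$onset_s,
    mrcp_present = present,
    true_pn_time_s = ifelse(present, pn_times, NA_real_),
    true_emg_onset_s = ifelse(present, emg_onsets, NA_real_)
  )
  attr(truth, "success_prob") <- success_prob
  attr(truth, "seed") <- seed

  structure(
    list(
      eeg = recording(eeg, rate = rate),
      emg = recording(matrix(emg, ncol = 1), rate = rate, labels = EMG_CHANNEL),
      events = plan,
      truth = truth
    ),
    class = "mrcp_subject"
  )
}

#' @export
print.mrcp_subject <- function(x, ...) {
  cat(sprintf(
    "<mrcp_subject> %d trials, %.0f s @ %g Hz, %d MRCP(s) planted\n",
    nrow(x$events), duration(x$eeg), x$eeg$rate, sum(x$truth$mrcp_present)
  ))
  invisible(x)
}

#' Synthesize a cohort on disk
#'
#' One EEG EDF, one EMG EDF, one event CSV and one ground-truth JSON per
#' subject x condition, plus a manifest. Per-file seeds are drawn from the
#' master seed, so a rerun with the same seed reproduces every file.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_subjects Number of subjects. Default 13.
#' @param conditions Condition labels. Default all three.
#' @param success_prob Named per-condition MRCP probabilities. Defaults are
#'   the study's mean per-condition success rates (0.67, 0.67, 0.63).
#' @param seed Master integer seed.
#' @param template,noise,timing,layout Generator settings.
#' @param rate Sampling rate in Hz.
#' @return Manifest tibble (one row per subject x condition with file paths),
#'   invisibly; also written to `manifest.csv`.
#' @export
synth_cohort <- function(out_dir, n_subjects = 13,
                         conditions = c("control", "phrase", "random"),
                         success_prob = c(control = 0.67, phrase = 0.67, random = 0.63),
                         seed = 1, template = mrcp_template_params(),
                         noise = noise_params(), timing = timing_spec(),
                         layout = speller_layout(), rate = 1200) {
  stopifnot(n_subjects >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(subject = seq_len(n_subjects), condition = conditions,
                      stringsAsFactors = FALSE)
  seeds <- withr::with_seed(seed, matrix(
    sample.int(.Machine$integer.max, 2 * nrow(grid)), ncol = 2
  ))
  rows <- purrr::pmap(
    list(grid$subject, grid$condition, seeds[, 1], seeds[, 2]),
    function(subj, cond, phrase_seed, synth_seed) {
      phrase <- plan_condition(cond, seed = phrase_seed)
      plan <- simulate_session(phrase, layout, timing, condition = cond)
      sp <- if (is.null(names(success_prob))) success_prob[1] else success_prob[[cond]]
      sub <- synth_subject(plan, template, noise, success_prob = sp,
                           seed = synth_seed, timing = timing, rate = rate)
      stem <- file.path(out_dir, sprintf("sub-%02d_cond-%s", subj, cond))
      write_edf(sub$eeg, paste0(stem, "_eeg.edf"))
      write_edf(sub$emg, paste0(stem, "_emg.edf"))
      write_events(sub$events, paste0(stem, "_events.csv"))
      write_ground_truth(sub$truth, paste0(stem, "_truth.json"))
      tibble::tibble(
        subject = sprintf("S%02d", subj), condition = cond,
        n_trials = nrow(plan), success_prob = sp, seed = synth_seed,
        eeg = paste0(stem, "_eeg.edf"), emg = paste0(stem, "_emg.edf"),
        events = paste0(stem, "_events.csv"), truth = paste0(stem, "_truth.json")
      )
    }
  )
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
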