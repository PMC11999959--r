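# Peak-negativity identification, per-trial acceptance criteria, success
# rate, and re-aligned epoch datasets.

#' Identify the peak negativity (PN) per trial
#'
#' The PN is the global minimum of the trace within the search window around
#' the cue; the earliest sample wins ties.
#'
#' @param epochs A cue-aligned `epoch_set`.
#' @param window Search window in seconds around the cue. Default `c(-2, 2)`.
#' @return Tibble with `trial_idx`, `pn_time_s`, `pn_amplitude_uv`.
#' @export
detect_pn <- function(epochs, window = c(-2, 2)) {
  stopifnot(inherits(epochs, "epoch_set"))
  mask <- epochs$time_s >= window[1] & epochs$time_s <= window[2]
  if (!any(mask)) abort("PN search window is empty")
  tsub <- epochs$time_s[mask]
  sub <- epochs$data[, mask, drop = FALSE]
  i_min <- apply(sub, 1, which.min) # which.min returns the first (earliest) minimum
  tibble::tibble(
    trial_idx = epochs$trial_idx,
    pn_time_s = tsub[i_min],
    pn_amplitude_uv = sub[cbind(seq_len(nrow(sub)), i_min)]
  )
}

#' Apply the four per-trial acceptance criteria
#'
#' A trial is successful when all of the following hold:
#' criterion 1 - both the PN and the EMG onset fall within +/- `pn_emg_window`
#' seconds of the cue (a missing EMG onset fails the criterion);
#' criterion 2 - the trace exhibits the MRCP morphology: both negative slopes
#' are negative (`NS1 < 0`, `NS2 < 0`) and the rebound slope is positive;
#' criterion 3 - the PN is a strict local minimum (every other sample within
#' `local_min_halfwidth_s` of the PN is larger);
#' and, as an exclusion rule, the PN must not occur more than
#' `-early_pn_cutoff` seconds before the cue (an MRCP peaking that early
#' cannot reflect the cued movement).
#'
#' @param epochs The cue-aligned `epoch_set` (used for the local-minimum
#'   check).
#' @param pn Tibble from [detect_pn()].
#' @param emg Tibble from [detect_emg_onset()].
#' @param features Tibble from [extract_features()] (PN-aligned slopes).
#' @param pn_emg_window Half-width of the cue window for criterion 1, s.
#'   Default 0.5.
#' @param early_pn_cutoff Rejection cutoff for early PNs, s. Default -1.
#' @param local_min_halfwidth_s Neighborhood half-width for criterion 3, s.
#'   Default 0.05.
#' @return Tibble with one row per trial: `trial_idx`, `pn_time_s`,
#'   `pn_amplitude_uv`, `emg_onset_s`, flags `c1`, `c2`, `c3`,
#'   `rejected_early_pn`, and `success`.
#' @export
evaluate_criteria <- function(epochs, pn, emg, features,
                              pn_emg_window = 0.5, early_pn_cutoff = -1,
                              local_min_halfwidth_s = 0.05) {
  stopifnot(inherits(epochs, "epoch_set"))
  tbl <- pn |>
    dplyr::left_join(emg, by = "trial_idx") |>
    dplyr::left_join(
      dplyr::select(features, "trial_idx", "ns1_uv_s", "ns2_uv_s", "rebound_uv_s"),
      by = "trial_idx"
    )
  stopifnot(identical(tbl$trial_idx, epochs$trial_idx))
  c3 <- vapply(seq_len(nrow(tbl)), function(i) {
    pn_strict_local_min(epochs$data[i, ], epochs$time_s, tbl$pn_time_s[i],
                        local_min_halfwidth_s)
  }, logical(1))
  tbl |>
    dplyr::mutate(
      c1 = !is.na(.data$emg_onset_s) &
        abs(.data$pn_time_s) <= pn_emg_window &
        abs(.data$emg_onset_s) <= pn_emg_window,
      c2 = dplyr::coalesce(
        .data$ns1_uv_s < 0 & .data$ns2_uv_s < 0 & .data$rebound_uv_s > 0,
        FALSE
      ),
      c3 = c3,
      rejected_early_pn = .data$pn_time_s < early_pn_cutoff,
      success = .data$c1 & .data$c2 & .data$c3 & !.data$rejected_early_pn
    ) |>
    dplyr::select(
      "trial_idx", "pn_time_s", "pn_amplitude_uv", "emg_onset_s",
      "c1", "c2", "c3", "rejected_early_pn", "success"
    )
}

pn_strict_local_min <- function(x, time_s, pn_time, halfwidth) {
  i_pn <- which.min(abs(time_s - pn_time))
  nb <- which(abs(time_s - time_s[i_pn]) <= halfwidth)
  nb <- setdiff(nb, i_pn)
  length(nb) > 0 && all(x[nb] > x[i_pn])
}

#' Success rate over a set of trial assessments
#'
#' Counts successful trials and reports the percentage of the total, rounded
#' to the nearest integer (26 trials per session in the study design). If the
#' assessment table carries `subject`, `condition` or `processing` columns the
#' summary is grouped by them.
#'
#' @param assessments Tibble from [evaluate_criteria()] (rows may be pooled
#'   across subjects/conditions with identifier columns added).
#' @return Tibble with `n_success`, `n_total`, `success_rate_pct`.
#' @export
success_rate <- function(assessments) {
  if (nrow(assessments) == 0) abort("no trials to summarize")
  keys <- intersect(c("subject", "condition", "processing"), names(assessments))
  assessments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_success = sum(.data$success),
      n_total = dplyr::n(),
      success_rate_pct = round(100 * sum(.data$success) / dplyr::n()),
      .groups = "drop"
    )
}

#' Re-align epochs to the cue, the EMG onset, or the peak negativity
#'
#' Each trial is re-windowed around its per-trial reference time (2 s before
#' to 1.5 s after by default). Trials whose window exceeds the source epoch
#' are dropped with a warning.
#'
#' @param epochs A cue-aligned `epoch_set`.
#' @param ref_times Tibble with `trial_idx` and a reference-time column:
#'   `pn_time_s` (reference "pn") or `emg_onset_s` (reference "emg");
#'   ignored for reference "cue".
#' @param reference One of `"pn"`, `"emg"`, `"cue"`.
#' @param window Window in seconds around the reference. Default
#'   `c(-2, 1.5)` (4,200 samples at 1,200 Hz).
#' @return An `epoch_set` re-referenced to the chosen time point.
#' @export
realign_epochs <- function(epochs, ref_times = NULL,
                           reference = c("pn", "emg", "cue"),
                           window = c(-2, 1.5)) {
  stopifnot(inherits(epochs, "epoch_set"))
  reference <- match.arg(reference)
  col <- switch(reference, pn = "pn_time_s", emg = "emg_onset_s", cue = NULL)
  if (reference == "cue") {
    refs <- rep(0, nrow(epochs$data))
  } else {
    if (is.null(ref_times) || !col %in% names(ref_times)) {
      abort(sprintf("`ref_times` with column '%s' is required for reference '%s'", col, reference))
    }
    m <- match(epochs$trial_idx, ref_times$trial_idx)
    refs <- ref_times[[col]][m]
    if (anyNA(refs)) {
      abort(sprintf(
        "missing %s reference time for trial(s): %s", reference,
        paste(epochs$trial_idx[is.na(refs)], collapse = ", ")
      ))
    }
  }
  n_samp <- round((window[2] - window[1]) * epochs$rate)
  i_ref <- round((refs - epochs$time_s[1]) * epochs$rate) + 1L
  starts <- i_ref + round(window[1] * epochs$rate)
  keep <- starts >= 1L & (starts + n_samp - 1L) <= ncol(epochs$data)
  if (!all(keep)) {
    warn(sprintf(
      "dropping trial(s) whose re-aligned window exceeds the epoch: %s",
      paste(epochs$trial_idx[!keep], collapse = ", ")
    ))
  }
  data <- t(vapply(which(keep), function(i) {
    epochs$data[i, starts[i]:(starts[i] + n_samp - 1L)]
  }, numeric(n_samp)))
  time_s <- window[1] + (seq_len(n_samp) - 1L) / epochs$rate
  new_epoch_set(data, time_s, epochs$rate, reference = reference,
                trial_idx = epochs$trial_idx[keep], channel = epochs$channel,
                condition = epochs$condition, subject = epochs$subject)
}
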