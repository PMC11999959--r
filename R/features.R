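# MRCP descriptors: PN amplitude, NS1/NS2/rebound slopes, peak-to-peak.

#' Slope windows for the MRCP features
#'
#' Time intervals relative to the peak negativity over which the three slopes
#' are fit: the early readiness-potential slope NS1, the late negative slope
#' NS2 ending at the PN, and the post-PN rebound. Defaults follow the
#' conventional MRCP component partition (early BP / late NS' / rebound).
#'
#' @param ns1 NS1 interval, s. Default `c(-2, -0.5)`.
#' @param ns2 NS2 interval, s. Default `c(-0.5, 0)`.
#' @param rebound Rebound interval, s. Default `c(0, 1)`.
#' @return An object of class `slope_windows`.
#' @export
slope_windows <- function(ns1 = c(-2, -0.5), ns2 = c(-0.5, 0),
                          rebound = c(0, 1)) {
  for (w in list(ns1, ns2, rebound)) {
    if (length(w) != 2 || w[1] >= w[2]) abort("each window must be an increasing pair")
  }
  if (ns1[2] > ns2[1] || ns2[2] > rebound[1]) {
    abort("windows must be ordered ns1 <= ns2 <= rebound without overlap")
  }
  structure(list(ns1 = ns1, ns2 = ns2, rebound = rebound),
            class = "slope_windows")
}

ols_slope <- function(x, time_s, window) {
  mask <- time_s >= window[1] & time_s <= window[2]
  if (sum(mask) < 2) {
    abort(sprintf("slope window [%g, %g] s contains fewer than 2 samples",
                  window[1], window[2]))
  }
  tt <- time_s[mask]
  y <- x[mask]
  tc <- tt - mean(tt)
  sum(tc * y) / sum(tc^2)
}

#' Extract the five MRCP features from PN-aligned trials
#'
#' Per trial: `pn_uv` is the value at time 0 (the PN); each slope is the
#' least-squares linear fit over its window; `pp_uv` is max - min over the
#' peak-to-peak window (2 s before to 2 s after the PN), clipped to the
#' epoch's actual extent.
#'
#' @param aligned A PN-aligned `epoch_set` (see [realign_epochs()]).
#' @param windows A [slope_windows()].
#' @param pp_window Peak-to-peak window, s. Default `c(-2, 2)`.
#' @return Tibble with `trial_idx`, `pn_uv`, `ns1_uv_s`, `ns2_uv_s`,
#'   `rebound_uv_s`, `pp_uv`.
#' @export
extract_features <- function(aligned, windows = slope_windows(),
                             pp_window = c(-2, 2)) {
  stopifnot(inherits(aligned, "epoch_set"))
  t0 <- which.min(abs(aligned$time_s))
  pp_lo <- max(pp_window[1], min(aligned$time_s))
  pp_hi <- min(pp_window[2], max(aligned$time_s))
  if (pp_lo >= pp_hi) abort("peak-to-peak window is empty after clipping")
  pp_mask <- aligned$time_s >= pp_lo & aligned$time_s <= pp_hi
  rows <- lapply(seq_len(nrow(aligned$data)), function(i) {
    x <- aligned$data[i, ]
    tibble::tibble(
      trial_idx = aligned$trial_idx[i],
      pn_uv = x[t0],
      ns1_uv_s = ols_slope(x, aligned$time_s, windows$ns1),
      ns2_uv_s = ols_slope(x, aligned$time_s, windows$ns2),
      rebound_uv_s = ols_slope(x, aligned$time_s, windows$rebound),
      pp_uv = max(x[pp_mask]) - min(x[pp_mask])
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-subject, per-condition feature means
#'
#' Arithmetic mean of each feature over the validated trials of every
#' subject-condition cell, per processing path. Missing cells (no validated
#' trials) are reported with a warning.
#'
#' @param features Feature tibble carrying `subject`, `condition` (and
#'   optionally `processing`) identifier columns.
#' @return Tibble with one row per subject x condition (x processing) and the
#'   mean of each feature column.
#' @export
subject_condition_means <- function(features) {
  keys <- intersect(c("processing", "subject", "condition"), names(features))
  if (!all(c("subject", "condition") %in% keys)) {
    abort("`features` must carry `subject` and `condition` columns")
  }
  feat_cols <- intersect(
    c("pn_uv", "ns1_uv_s", "ns2_uv_s", "rebound_uv_s", "pp_uv"), names(features)
  )
  means <- features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(feat_cols), mean),
      n_trials = dplyr::n(), .groups = "drop"
    )
  full <- tidyr::expand_grid(
    subject = unique(features$subject),
    condition = unique(features$condition)
  )
  miss <- dplyr::anti_join(full, means, by = c("subject", "condition"))
  if (nrow(miss) > 0) {
    warn(sprintf(
      "no validated trials for cell(s): %s",
      paste(paste(miss$subject, miss$condition, sep = "/"), collapse = ", ")
    ))
  }
  means
}
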