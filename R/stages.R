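# File-based pipeline stages. Each stage consumes/produces on-disk artifacts
# under config$out_dir so the steps can be run independently (and are what
# the command-line wrapper dispatches to). Running simulate -> preprocess ->
# validate -> features -> stats reproduces a `run_study()` call with
# `write_raw = TRUE` (validation stages work from the raw files and apply the
# configured filters themselves, so the EDF 16-bit quantization is applied
# exactly once on either route).

raw_manifest <- function(config) {
  path <- file.path(config$out_dir, "raw", "manifest.csv")
  if (!file.exists(path)) {
    abort(sprintf("missing %s: run the simulate stage first", path))
  }
  readr::read_csv(path, col_types = readr::cols())
}

#' Pipeline stages (file-based)
#'
#' `stage_simulate()` writes the synthetic cohort (EDF + event CSV +
#' ground-truth JSON per subject-condition) under `out_dir/raw`.
#' `stage_preprocess()` writes notch/band-pass filtered EEG and the
#' large-Laplacian channel under `out_dir/derived` for inspection.
#' `stage_validate()` writes per-trial assessments and success-rate tables.
#' `stage_features()` writes trial features, subject-condition means and the
#' PN-aligned subject mean traces. `stage_stats()` reads those tables and
#' writes the Friedman/post-hoc results, grand averages and the statistical
#' map.
#'
#' @param config A [study_config()].
#' @return Each stage returns its main result invisibly.
#' @export
stage_simulate <- function(config = study_config()) {
  synth_cohort(
    file.path(config$out_dir, "raw"), n_subjects = config$n_subjects,
    conditions = config$conditions, success_prob = config$success_prob,
    seed = config$seed, template = config$template, noise = config$noise,
    timing = config$timing, layout = config$layout, rate = config$rate
  )
}

#' @rdname stage_simulate
#' @export
stage_preprocess <- function(config = study_config()) {
  man <- raw_manifest(config)
  dir.create(file.path(config$out_dir, "derived"), showWarnings = FALSE,
             recursive = TRUE)
  for (i in seq_len(nrow(man))) {
    eeg <- read_edf(man$eeg[i])
    eeg_f <- if (length(config$filters) > 0) apply_filter(eeg, config$filters) else eeg
    stem <- file.path(config$out_dir, "derived", basename(man$eeg[i]))
    write_edf(eeg_f, sub("_eeg\\.edf$", "_eeg_filtered.edf", stem))
    write_edf(large_laplacian(eeg_f), sub("_eeg\\.edf$", "_lap.edf", stem))
  }
  invisible(man)
}

process_from_files <- function(config) {
  man <- raw_manifest(config)
  res <- lapply(seq_len(nrow(man)), function(i) {
    process_subject(
      read_edf(man$eeg[i]), read_edf(man$emg[i]), read_events(man$events[i]),
      config, subject = man$subject[i]
    )
  })
  list(
    assessments = dplyr::bind_rows(lapply(res, `[[`, "assessments")),
    features = dplyr::bind_rows(lapply(res, `[[`, "features")),
    aligned = purrr::list_flatten(lapply(seq_len(nrow(man)), function(i) {
      al <- res[[i]]$aligned
      stats::setNames(al, paste(man$subject[i], man$condition[i], names(al), sep = "_"))
    }))
  )
}

#' @rdname stage_simulate
#' @export
stage_validate <- function(config = study_config()) {
  res <- process_from_files(config)
  success <- success_rate(res$assessments)
  success_wide <- success |>
    dplyr::select("processing", "subject", "condition", "success_rate_pct") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "success_rate_pct")
  readr::write_csv(res$assessments,
                   file.path(config$out_dir, "trial_assessments.csv"))
  readr::write_csv(success, file.path(config$out_dir, "success_rates.csv"))
  readr::write_csv(success_wide,
                   file.path(config$out_dir, "success_rates_wide.csv"))
  invisible(success)
}

#' @rdname stage_simulate
#' @export
stage_features <- function(config = study_config()) {
  res <- process_from_files(config)
  valid_feats <- res$features |>
    dplyr::semi_join(
      dplyr::filter(res$assessments, .data$success),
      by = c("subject", "condition", "processing", "trial_idx")
    )
  means <- subject_condition_means(valid_feats)
  traces <- dplyr::bind_rows(lapply(config$processing, function(proc) {
    sets <- res$aligned[grepl(paste0("_", proc, "$"), names(res$aligned))]
    sets <- sets[vapply(sets, function(e) nrow(e$data) > 0, logical(1))]
    dplyr::mutate(subject_mean_traces(sets), processing = proc)
  }))
  readr::write_csv(res$features, file.path(config$out_dir, "trial_features.csv"))
  readr::write_csv(means, file.path(config$out_dir, "subject_condition_means.csv"))
  readr::write_csv(traces, file.path(config$out_dir, "spm_input_traces.csv"))
  readr::write_csv(
    dplyr::distinct(traces, .data$processing, .data$subject, .data$condition),
    file.path(config$out_dir, "spm_input_manifest.csv")
  )
  invisible(means)
}

#' @rdname stage_simulate
#' @export
stage_stats <- function(config = study_config()) {
  means <- readr::read_csv(
    file.path(config$out_dir, "subject_condition_means.csv"),
    col_types = readr::cols()
  )
  traces <- readr::read_csv(
    file.path(config$out_dir, "spm_input_traces.csv"),
    col_types = readr::cols()
  )
  feat_cols <- intersect(
    c("pn_uv", "ns1_uv_s", "ns2_uv_s", "rebound_uv_s", "pp_uv"), names(means)
  )
  friedman_tbl <- list(); posthoc_tbl <- list()
  spm <- list(); grand <- list()
  for (proc in unique(means$processing)) {
    m_proc <- means[means$processing == proc, ]
    complete <- m_proc |>
      dplyr::count(.data$subject) |>
      dplyr::filter(.data$n == length(unique(m_proc$condition)))
    m_proc <- m_proc[m_proc$subject %in% complete$subject, ]
    for (fc in feat_cols) {
      fr <- friedman_mrcp(m_proc, value = fc, subject = "subject",
                          condition = "condition", feature = fc)
      row <- tidy(fr); row$processing <- proc
      friedman_tbl[[paste(proc, fc)]] <- row
      if (fr$p_value < config$alpha) {
        conds <- unique(m_proc$condition)
        pairs <- utils::combn(conds, 2)
        adj <- bonferroni_alpha(config$alpha, ncol(pairs))
        wide <- tidyr::pivot_wider(
          m_proc[, c("subject", "condition", fc)],
          names_from = "condition", values_from = dplyr::all_of(fc)
        )
        for (pi in seq_len(ncol(pairs))) {
          wt <- wilcoxon_signed_rank(
            wide[[pairs[1, pi]]], wide[[pairs[2, pi]]],
            comparison = paste(pairs[1, pi], "vs", pairs[2, pi])
          )
          row <- tidy(wt)
          row$feature <- fc; row$processing <- proc; row$adjusted_alpha <- adj
          posthoc_tbl[[paste(proc, fc, pi)]] <- row
        }
      }
    }
    tr <- traces[traces$processing == proc, ]
    grand[[proc]] <- dplyr::mutate(grand_average(tr), processing = proc)
    spm[[proc]] <- spm_anova(tr, alpha = config$alpha,
                             n_perm = config$spm_n_perm,
                             seed = config$seed + 1,
                             variant = config$spm_variant)
  }
  friedman_tbl <- dplyr::bind_rows(friedman_tbl)
  readr::write_csv(friedman_tbl, file.path(config$out_dir, "friedman.csv"))
  if (length(posthoc_tbl) > 0) {
    readr::write_csv(dplyr::bind_rows(posthoc_tbl),
                     file.path(config$out_dir, "posthoc_wilcoxon.csv"))
  }
  readr::write_csv(dplyr::bind_rows(grand),
                   file.path(config$out_dir, "grand_average.csv"))
  for (proc in names(spm)) {
    s <- spm[[proc]]
    readr::write_csv(
      tibble::tibble(time_s = s$time_s, f = s$f, threshold = s$threshold),
      file.path(config$out_dir, sprintf("spm_curve_%s.csv", proc))
    )
    readr::write_csv(s$clusters,
                     file.path(config$out_dir, sprintf("spm_clusters_%s.csv", proc)))
  }
  invisible(list(friedman = friedman_tbl, spm = spm))
}
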