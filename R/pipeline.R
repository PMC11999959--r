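# Study orchestration: simulate -> preprocess -> detect -> validate ->
# features -> stats, as one configured, reproducible run.

#' Study configuration
#'
#' Collects every tunable of the pipeline with the study defaults: 13
#' subjects, three conditions, 1,200 Hz, notch + band-pass preprocessing,
#' both processing paths (plain Cz and large-Laplacian Cz).
#'
#' @param out_dir Output directory for run artifacts.
#' @param n_subjects Number of synthetic subjects. Default 13.
#' @param conditions Conditions to simulate. Default all three.
#' @param success_prob Named per-condition planted MRCP probabilities.
#' @param seed Master seed; all per-subject seeds derive from it.
#' @param rate Sampling rate, Hz. Default 1200.
#' @param template,noise,timing,layout Generator settings.
#' @param filters List of [filter_spec()] applied in order to the continuous
#'   EEG (use `list()` to disable filtering).
#' @param emg [emg_onset_params()].
#' @param windows [slope_windows()].
#' @param pn_search PN search window around the cue, s. Default `c(-2, 2)`.
#' @param epoch_window Cue epoch window, s. Default `c(-4, 5)`.
#' @param align_window Re-aligned epoch window, s. Default `c(-2, 1.5)`.
#' @param processing Processing paths, subset of `c("cz", "laplacian")`.
#' @param spm_n_perm,spm_variant,alpha Statistics options.
#' @param write_raw Write synthetic recordings as EDF/CSV/JSON and process
#'   from the written files (so file-based stage runs reproduce the study
#'   exactly, including EDF quantization)? Default `FALSE`.
#' @param save_figures Save grand-average and statistical-map figures as PNG?
#'   Default `FALSE`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(out_dir = tempfile("mrcp-run-"), n_subjects = 13,
                         conditions = c("control", "phrase", "random"),
                         success_prob = c(control = 0.67, phrase = 0.67, random = 0.63),
                         seed = 1, rate = 1200,
                         template = mrcp_template_params(),
                         noise = noise_params(), timing = timing_spec(),
                         layout = speller_layout(),
                         filters = default_filters(),
                         emg = emg_onset_params(), windows = slope_windows(),
                         pn_search = c(-2, 2), epoch_window = c(-4, 5),
                         align_window = c(-2, 1.5),
                         processing = c("cz", "laplacian"),
                         spm_n_perm = 199, spm_variant = "rm", alpha = 0.05,
                         write_raw = FALSE, save_figures = FALSE) {
  processing <- match.arg(processing, c("cz", "laplacian"), several.ok = TRUE)
  structure(
    list(out_dir = out_dir, n_subjects = n_subjects, conditions = conditions,
         success_prob = success_prob, seed = seed, rate = rate,
         template = template, noise = noise, timing = timing, layout = layout,
         filters = filters, emg = emg, windows = windows,
         pn_search = pn_search, epoch_window = epoch_window,
         align_window = align_window, processing = processing,
         spm_n_perm = spm_n_perm, spm_variant = spm_variant, alpha = alpha,
         write_raw = write_raw, save_figures = save_figures),
    class = "study_config"
  )
}

#' Process one subject-condition recording through the validation chain
#'
#' Filters the continuous EEG, derives the requested processing paths (plain
#' Cz and/or large-Laplacian Cz), epochs around the trials' reference times,
#' demeans, detects the EMG onset and the peak negativity, re-aligns to the
#' PN, extracts the five features and applies the acceptance criteria.
#'
#' The trial reference (epoch time 0) is the *expected movement time*: the
#' column/row onset plus the selector's midpoint offset. The cue event marks
#' the bar entering the target column/row, but the subject moves when the bar
#' is around the cell midpoint, so the acceptance windows (PN and EMG onset
#' within +/- 0.5 s) are anchored to that expected movement time.
#'
#' @param eeg,emg EEG and EMG [recording()]s.
#' @param events Cue event tibble.
#' @param config A [study_config()].
#' @param subject Subject label carried into all outputs.
#' @return List with `assessments` and `features` tibbles (both carrying
#'   `subject`, `condition`, `processing`), and `aligned`, a named list of
#'   PN-aligned epoch sets of the successful trials per processing path.
#' @export
process_subject <- function(eeg, emg, events, config = study_config(),
                            subject = "S01") {
  condition <- if ("condition" %in% names(events)) events$condition[1] else NA_character_
  eeg_f <- if (length(config$filters) > 0) apply_filter(eeg, config$filters) else eeg
  # anchor trials at the expected movement time (cue + midpoint offset)
  events <- dplyr::mutate(
    events, onset_s = .data$onset_s + config$timing$midpoint_offset_s
  )
  emg_epochs <- segment_epochs(emg, events, channel = EMG_CHANNEL,
                               window = config$epoch_window)
  emg_onsets <- detect_emg_onset(emg_epochs, config$emg)
  out_assess <- list()
  out_feat <- list()
  aligned_success <- list()
  for (proc in config$processing) {
    rec <- if (proc == "laplacian") large_laplacian(eeg_f) else eeg_f
    channel <- if (proc == "laplacian") "Cz_lap" else "Cz"
    epochs <- segment_epochs(rec, events, channel = channel,
                             window = config$epoch_window) |>
      demean_epochs()
    epochs$subject <- subject
    pn <- detect_pn(epochs, window = config$pn_search)
    aligned <- realign_epochs(epochs, pn, reference = "pn",
                              window = config$align_window)
    feats <- extract_features(aligned, config$windows)
    assess <- evaluate_criteria(epochs, pn, emg_onsets, feats)
    assess$subject <- subject; assess$condition <- condition
    assess$processing <- proc
    feats$subject <- subject; feats$condition <- condition
    feats$processing <- proc
    ok <- assess$trial_idx[assess$success]
    sel <- aligned$trial_idx %in% ok
    asel <- aligned
    asel$data <- aligned$data[sel, , drop = FALSE]
    asel$trial_idx <- aligned$trial_idx[sel]
    out_assess[[proc]] <- assess
    out_feat[[proc]] <- feats[feats$trial_idx %in% aligned$trial_idx, ]
    aligned_success[[proc]] <- asel
  }
  list(
    assessments = dplyr::bind_rows(out_assess),
    features = dplyr::bind_rows(out_feat),
    aligned = aligned_success
  )
}

#' Run the full synthetic study
#'
#' Simulates the cohort, runs the complete validation chain for every
#' subject-condition recording and both processing paths, and writes the
#' result tables: per-trial assessments, success-rate tables (long and wide),
#' trial features and subject-condition means, Friedman tests per feature
#' with Wilcoxon signed-rank post-hocs (Bonferroni-corrected) where the
#' omnibus is significant, grand averages, the pointwise ANOVA statistical
#' map with permutation clusters, and a ground-truth-versus-detected report.
#' All randomness flows from `config$seed`, so a rerun reproduces every
#' output file.
#'
#' @param config A [study_config()].
#' @return An object of class `mrcp_study` (list of all result tibbles and
#'   fitted objects), invisibly. Files are written under `config$out_dir`.
#' @export
run_study <- function(config = study_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(subject = seq_len(config$n_subjects),
                      condition = config$conditions, stringsAsFactors = FALSE)
  seeds <- withr::with_seed(config$seed, matrix(
    sample.int(.Machine$integer.max, 2 * nrow(grid)), ncol = 2
  ))
  assessments <- list(); features <- list(); aligned_sets <- list()
  truth_rows <- list()
  raw_dir <- file.path(config$out_dir, "raw")
  if (config$write_raw) dir.create(raw_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(grid))) {
    subj_lab <- sprintf("S%02d", grid$subject[i])
    cond <- grid$condition[i]
    phrase <- plan_condition(cond, seed = seeds[i, 1])
    plan <- simulate_session(phrase, config$layout, config$timing,
                             condition = cond)
    sp <- if (is.null(names(config$success_prob))) config$success_prob[1] else
      config$success_prob[[cond]]
    sub <- synth_subject(plan, config$template, config$noise,
                         success_prob = sp, seed = seeds[i, 2],
                         timing = config$timing, rate = config$rate)
    if (config$write_raw) {
      stem <- file.path(raw_dir, sprintf("sub-%02d_cond-%s", grid$subject[i], cond))
      write_edf(sub$eeg, paste0(stem, "_eeg.edf"))
      write_edf(sub$emg, paste0(stem, "_emg.edf"))
      write_events(sub$events, paste0(stem, "_events.csv"))
      write_ground_truth(sub$truth, paste0(stem, "_truth.json"))
      # process what the files contain, so file-based stage runs match exactly
      sub$eeg <- read_edf(paste0(stem, "_eeg.edf"))
      sub$emg <- read_edf(paste0(stem, "_emg.edf"))
      sub$events <- read_events(paste0(stem, "_events.csv"))
    }
    res <- process_subject(sub$eeg, sub$emg, sub$events, config,
                           subject = subj_lab)
    assessments[[i]] <- res$assessments
    features[[i]] <- res$features
    tr <- sub$truth
    tr$subject <- subj_lab; tr$condition <- cond
    truth_rows[[i]] <- tr
    for (proc in names(res$aligned)) {
      e <- res$aligned[[proc]]
      e$subject <- subj_lab
      aligned_sets[[paste(subj_lab, cond, proc, sep = "_")]] <- e
    }
  }
  assessments <- dplyr::bind_rows(assessments)
  features <- dplyr::bind_rows(features)
  truth <- dplyr::bind_rows(truth_rows)

  success <- success_rate(assessments)
  success_wide <- success |>
    dplyr::select("processing", "subject", "condition", "success_rate_pct") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "success_rate_pct")

  valid_feats <- features |>
    dplyr::semi_join(
      dplyr::filter(assessments, .data$success),
      by = c("subject", "condition", "processing", "trial_idx")
    )
  means <- subject_condition_means(valid_feats)

  feat_cols <- c("pn_uv", "ns1_uv_s", "ns2_uv_s", "rebound_uv_s", "pp_uv")
  friedman_tbl <- list(); posthoc_tbl <- list()
  for (proc in config$processing) {
    m_proc <- means[means$processing == proc, ]
    complete <- m_proc |>
      dplyr::count(.data$subject) |>
      dplyr::filter(.data$n == length(config$conditions))
    m_proc <- m_proc[m_proc$subject %in% complete$subject, ]
    for (fc in feat_cols) {
      fr <- friedman_mrcp(m_proc, value = fc, subject = "subject",
                          condition = "condition", feature = fc)
      row <- tidy(fr); row$processing <- proc
      friedman_tbl[[paste(proc, fc)]] <- row
      if (fr$p_value < config$alpha) {
        pairs <- utils::combn(config$conditions, 2)
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
  }
  friedman_tbl <- dplyr::bind_rows(friedman_tbl)
  posthoc_tbl <- if (length(posthoc_tbl)) dplyr::bind_rows(posthoc_tbl) else
    tibble::tibble()

  mean_traces <- list(); grand <- list(); spm <- list()
  for (proc in config$processing) {
    sets <- aligned_sets[grepl(paste0("_", proc, "$"), names(aligned_sets))]
    sets <- sets[vapply(sets, function(e) nrow(e$data) > 0, logical(1))]
    tr <- subject_mean_traces(sets)
    complete <- tr |>
      dplyr::distinct(.data$subject, .data$condition) |>
      dplyr::count(.data$subject) |>
      dplyr::filter(.data$n == length(config$conditions))
    if (nrow(complete) < config$n_subjects) {
      warn(sprintf(
        "%s path: %d subject(s) lack successful trials in some condition and are dropped from the statistical map",
        proc, config$n_subjects - nrow(complete)
      ))
    }
    tr_c <- tr[tr$subject %in% complete$subject, ]
    mean_traces[[proc]] <- dplyr::mutate(tr_c, processing = proc)
    grand[[proc]] <- dplyr::mutate(grand_average(tr_c), processing = proc)
    spm[[proc]] <- spm_anova(tr_c, alpha = config$alpha,
                             n_perm = config$spm_n_perm,
                             seed = config$seed + 1,
                             variant = config$spm_variant)
  }
  mean_traces <- dplyr::bind_rows(mean_traces)
  grand <- dplyr::bind_rows(grand)

  detected_pn <- assessments |>
    dplyr::select("subject", "condition", "processing", "trial_idx",
                  "pn_time_s", "emg_onset_s", "success")
  truth_report <- truth |>
    dplyr::left_join(detected_pn, by = c("subject", "condition", "trial_idx")) |>
    dplyr::mutate(
      # detected minus planted, both relative to the expected movement time
      pn_error_s = .data$pn_time_s -
        (.data$true_pn_time_s - .data$onset_s - config$timing$midpoint_offset_s),
      emg_error_s = .data$emg_onset_s -
        (.data$true_emg_onset_s - .data$onset_s - config$timing$midpoint_offset_s)
    )

  out <- list(
    config = config, assessments = assessments, features = features,
    success = success, success_wide = success_wide, means = means,
    friedman = friedman_tbl, posthoc = posthoc_tbl,
    mean_traces = mean_traces, grand_average = grand, spm = spm,
    truth = truth, truth_report = truth_report
  )
  class(out) <- "mrcp_study"
  write_study_outputs(out)
  invisible(out)
}

write_study_outputs <- function(study) {
  dir_out <- study$config$out_dir
  wr <- function(x, name) readr::write_csv(x, file.path(dir_out, name))
  wr(study$assessments, "trial_assessments.csv")
  wr(study$success, "success_rates.csv")
  wr(study$success_wide, "success_rates_wide.csv")
  wr(study$features, "trial_features.csv")
  wr(study$means, "subject_condition_means.csv")
  wr(study$friedman, "friedman.csv")
  if (nrow(study$posthoc) > 0) wr(study$posthoc, "posthoc_wilcoxon.csv")
  wr(study$mean_traces, "spm_input_traces.csv")
  wr(dplyr::distinct(study$mean_traces, .data$processing, .data$subject,
                     .data$condition),
     "spm_input_manifest.csv")
  wr(study$grand_average, "grand_average.csv")
  for (proc in names(study$spm)) {
    s <- study$spm[[proc]]
    readr::write_csv(
      tibble::tibble(time_s = s$time_s, f = s$f, threshold = s$threshold),
      file.path(dir_out, sprintf("spm_curve_%s.csv", proc))
    )
    readr::write_csv(s$clusters,
                     file.path(dir_out, sprintf("spm_clusters_%s.csv", proc)))
  }
  wr(study$truth_report, "truth_report.csv")
  cfg <- study$config
  cfg_list <- lapply(unclass(cfg), function(v) if (is.list(v)) unclass(v) else v)
  cfg_list$layout <- NULL
  yaml::write_yaml(cfg_list, file.path(dir_out, "config.yaml"))
  log_lines <- c(
    sprintf("run completed: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("config hash: %s", rlang::hash(cfg_list)),
    sprintf("master seed: %d", cfg$seed),
    sprintf("subjects x conditions: %d x %d", cfg$n_subjects, length(cfg$conditions)),
    sprintf("processing paths: %s", paste(cfg$processing, collapse = ", "))
  )
  writeLines(log_lines, file.path(dir_out, "run_log.txt"))
  if (isTRUE(study$config$save_figures)) {
    try(save_study_figures(study), silent = TRUE)
  }
  invisible(study)
}

save_study_figures <- function(study) {
  dir_out <- study$config$out_dir
  for (proc in names(study$spm)) {
    ga <- study$grand_average[study$grand_average$processing == proc, ]
    p1 <- plot_grand_average(ga)
    ggplot2::ggsave(file.path(dir_out, sprintf("grand_average_%s.png", proc)),
                    p1, width = 8, height = 4, dpi = 120)
    p2 <- autoplot(study$spm[[proc]])
    ggplot2::ggsave(file.path(dir_out, sprintf("spm_%s.png", proc)),
                    p2, width = 8, height = 4, dpi = 120)
  }
  invisible(study)
}

#' @export
print.mrcp_study <- function(x, ...) {
  cat(sprintf(
    "<mrcp_study> %d subject(s) x %d condition(s), paths: %s\n",
    x$config$n_subjects, length(x$config$conditions),
    paste(x$config$processing, collapse = ", ")
  ))
  cat("mean success rate (%) by condition and processing:\n")
  print(
    x$success |>
      dplyr::group_by(.data$processing, .data$condition) |>
      dplyr::summarise(mean_pct = round(mean(.data$success_rate_pct), 1),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "mean_pct")
  )
  invisible(x)
}
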