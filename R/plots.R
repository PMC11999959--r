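# ggplot2 figure methods for epoch sets, grand averages and statistical maps.

#' Plot an epoch set
#'
#' Single trials as thin traces with the across-trial mean overlaid.
#'
#' @param object An `epoch_set`.
#' @param max_trials Thin to at most this many single trials. Default 30.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epoch_set
#' @export
autoplot.epoch_set <- function(object, max_trials = 30, ...) {
  tbl <- as_tibble.epoch_set(object)
  keep <- unique(tbl$trial_idx)
  if (length(keep) > max_trials) {
    keep <- keep[seq(1, length(keep), length.out = max_trials)]
  }
  m <- epoch_mean(object)
  ggplot2::ggplot(tbl[tbl$trial_idx %in% keep, ],
                  ggplot2::aes(x = .data$time_s, y = .data$value_uv,
                               group = .data$trial_idx)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.2) +
    ggplot2::geom_line(data = m, ggplot2::aes(group = NULL),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("time relative to %s (s)", object$reference),
      y = "amplitude (µV)",
      title = sprintf("%s epochs (%d trials)", object$channel %||% "",
                      nrow(object$data))
    ) +
    ggplot2::theme_minimal()
}

#' Grand-average figure
#'
#' Per-condition mean trace with a +/- 1 SD ribbon, in the layout used for
#' MRCP grand averages (negative up by convention is NOT applied; the y axis
#' is plain uV).
#'
#' @param ga Tibble from [grand_average()].
#' @return A ggplot object.
#' @export
plot_grand_average <- function(ga) {
  stopifnot(all(c("condition", "time_s", "mean_uv", "sd_uv") %in% names(ga)))
  ggplot2::ggplot(ga, ggplot2::aes(x = .data$time_s, y = .data$mean_uv,
                                   colour = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_uv - .data$sd_uv,
                                      ymax = .data$mean_uv + .data$sd_uv),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time relative to PN (s)", y = "amplitude (µV)",
                  colour = "condition", fill = "condition",
                  title = "Grand-average MRCP by condition") +
    ggplot2::theme_minimal()
}

#' Plot a statistical map
#'
#' The pointwise F curve with its parametric threshold and the significant
#' permutation clusters shaded.
#'
#' @param object An `mrcp_spm` from [spm_anova()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrcp_spm
#' @export
autoplot.mrcp_spm <- function(object, ...) {
  curve <- tibble::tibble(time_s = object$time_s, f = object$f)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$time_s, y = .data$f)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "time relative to PN (s)",
      y = sprintf("F(%d, %d)", object$df1, object$df2),
      title = sprintf("Pointwise %s ANOVA with permutation clusters",
                      object$variant)
    ) +
    ggplot2::theme_minimal()
  sig <- object$clusters[object$clusters$p_value <= object$alpha, ]
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_rect(
      data = sig,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.2, fill = "grey40"
    )
  }
  p
}
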