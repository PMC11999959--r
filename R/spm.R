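# Grand averages and pointwise one-way ANOVA over time with cluster-level
# permutation inference (a documented substitute for random-field-theory
# thresholds: the pointwise threshold is the parametric F quantile, cluster
# p-values come from within-subject permutation of condition labels).

#' Per-subject, per-condition mean traces
#'
#' Averages the trials of each epoch set; with 13 subjects and 3 conditions
#' this yields the 39 mean traces entering the statistical map.
#'
#' @param epoch_sets List of `epoch_set` objects (one per subject-condition,
#'   each carrying its `subject` and `condition` fields).
#' @return Long tibble with `subject`, `condition`, `time_s`, `value_uv`,
#'   `n_trials`.
#' @export
subject_mean_traces <- function(epoch_sets) {
  dplyr::bind_rows(lapply(epoch_sets, function(e) {
    tr <- epoch_mean(e)
    tr[, c("subject", "condition", "time_s", "value_uv", "n_trials")]
  }))
}

#' Grand average traces per condition
#'
#' Pointwise mean and SD over the input traces (trials or subject means),
#' grouped by condition.
#'
#' @param traces Long tibble with `condition`, `time_s`, `value_uv` (one row
#'   per trace per time point), e.g. from [subject_mean_traces()] or
#'   [as_tibble.epoch_set()].
#' @return Tibble with `condition`, `time_s`, `mean_uv`, `sd_uv`, `n`.
#' @export
grand_average <- function(traces) {
  stopifnot(all(c("condition", "time_s", "value_uv") %in% names(traces)))
  if (nrow(traces) == 0) abort("no traces to average")
  traces |>
    dplyr::group_by(.data$condition, .data$time_s) |>
    dplyr::summarise(
      mean_uv = mean(.data$value_uv),
      sd_uv = sd(.data$value_uv),
      n = dplyr::n(),
      .groups = "drop"
    )
}

# x: matrix (n*k) x T with rows grouped subject-major; returns F curve
pointwise_f <- function(x, subj, cond, n, k, variant) {
  mj <- rowsum(x, cond) / n
  m <- colMeans(x)
  ssc <- n * colSums((mj - rep(m, each = k))^2)
  if (variant == "rm") {
    mi <- rowsum(x, subj) / k
    res <- x - mj[cond, , drop = FALSE] - mi[subj, , drop = FALSE] +
      rep(m, each = n * k)
    df2 <- (n - 1) * (k - 1)
  } else {
    res <- x - mj[cond, , drop = FALSE]
    df2 <- n * k - k
  }
  sse <- colSums(res^2)
  f <- (ssc / (k - 1)) / (sse / df2)
  f[!is.finite(f)] <- 0
  # identical condition traces give 0/0 up to rounding; report exactly no effect
  f[ssc <= 1e-12 * (colSums(x^2) / nrow(x) + 1e-300)] <- 0
  list(f = f, df1 = k - 1, df2 = df2)
}

# maximum cluster mass only (hot path of the permutation loop)
max_cluster_mass <- function(f, thr) {
  above <- f > thr
  if (!any(above)) return(0)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  max(vapply(keep, function(j) sum(f[starts[j]:ends[j]] - thr), numeric(1)))
}

find_clusters <- function(f, thr, time_s) {
  above <- f > thr
  if (!any(above)) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          mass = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble::tibble(
    start_s = time_s[starts[keep]],
    end_s = time_s[ends[keep]],
    mass = vapply(keep, function(j) {
      sum(f[starts[j]:ends[j]] - thr)
    }, numeric(1))
  )
}

#' Pointwise one-way ANOVA over time with permutation cluster inference
#'
#' Computes the repeated-measures (default) or pooled one-way F statistic at
#' every time point of the subject-condition mean traces, thresholds the
#' curve at the parametric F quantile `1 - alpha`, and assigns each
#' supra-threshold cluster a p-value from the permutation distribution of the
#' maximum cluster mass (sum of F minus threshold within a cluster) obtained
#' by permuting condition labels within subjects. If any cluster is
#' significant, pointwise post-hoc paired t curves are computed for every
#' condition pair at the Bonferroni-adjusted alpha.
#'
#' @param traces Long tibble from [subject_mean_traces()], or a 3-d array
#'   `subjects x conditions x time` (with a `time_s` attribute or unit time).
#' @param alpha Pointwise and family-wise significance level. Default 0.05.
#' @param n_perm Number of label permutations. Default 199.
#' @param seed Integer seed for the permutation draw.
#' @param variant `"rm"` (repeated measures, default) or `"pooled"`.
#' @param posthoc Compute paired t curves when clusters are significant?
#'   Default `TRUE`.
#' @return An object of class `mrcp_spm`: `time_s`, `f`, `threshold`, `df1`,
#'   `df2`, `clusters` (tibble with `start_s`, `end_s`, `mass`, `p_value`),
#'   `posthoc` (tibble or NULL), `n_perm`, `seed`, `variant`, `alpha`,
#'   `n_subjects`, `k_conditions`.
#' @export
spm_anova <- function(traces, alpha = 0.05, n_perm = 199, seed = 1,
                      variant = c("rm", "pooled"), posthoc = TRUE) {
  variant <- match.arg(variant)
  if (is.array(traces) && length(dim(traces)) == 3) {
    arr <- traces
    time_s <- attr(traces, "time_s") %||% seq_len(dim(arr)[3])
    subjects <- dimnames(arr)[[1]] %||% as.character(seq_len(dim(arr)[1]))
    conditions <- dimnames(arr)[[2]] %||% as.character(seq_len(dim(arr)[2]))
  } else {
    stopifnot(all(c("subject", "condition", "time_s", "value_uv") %in% names(traces)))
    subjects <- unique(traces$subject)
    conditions <- unique(traces$condition)
    time_s <- sort(unique(traces$time_s))
    arr <- array(NA_real_, c(length(subjects), length(conditions), length(time_s)))
    for (si in seq_along(subjects)) {
      for (ci in seq_along(conditions)) {
        sub <- traces[traces$subject == subjects[si] &
                        traces$condition == conditions[ci], ]
        if (nrow(sub) != length(time_s)) {
          abort("unbalanced design: every subject needs every condition on a common time axis")
        }
        arr[si, ci, ] <- sub$value_uv[order(sub$time_s)]
      }
    }
  }
  n <- dim(arr)[1]; k <- dim(arr)[2]; nt <- dim(arr)[3]
  if (k < 2 || n < 2) abort("need at least 2 subjects and 2 conditions")
  if (anyNA(arr)) abort("unbalanced design: missing subject-condition cells")
  subj <- rep(seq_len(n), each = k)
  cond <- rep(seq_len(k), times = n)
  x <- matrix(aperm(arr, c(2, 1, 3)), n * k, nt) # rows: (s1c1, s1c2, ..., snck)
  obs <- pointwise_f(x, subj, cond, n, k, variant)
  thr <- qf(1 - alpha, obs$df1, obs$df2)
  clusters <- find_clusters(obs$f, thr, time_s)
  if (nrow(clusters) > 0) {
    max_mass <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b) {
      perm <- as.integer(unlist(lapply(seq_len(n), function(s) {
        (s - 1L) * k + sample.int(k)
      })))
      fp <- pointwise_f(x[perm, , drop = FALSE], subj, cond, n, k, variant)$f
      max_cluster_mass(fp, thr)
    }, numeric(1)))
    clusters$p_value <- vapply(clusters$mass, function(m) {
      (1 + sum(max_mass >= m)) / (n_perm + 1)
    }, numeric(1))
  } else {
    clusters$p_value <- numeric(0)
  }
  post <- NULL
  if (posthoc && any(clusters$p_value <= alpha)) {
    pairs <- utils::combn(seq_len(k), 2)
    adj <- bonferroni_alpha(alpha, ncol(pairs))
    tcrit <- qt(1 - adj / 2, n - 1)
    post <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(pi) {
      d <- arr[, pairs[1, pi], ] - arr[, pairs[2, pi], ]
      tval <- colMeans(d) / (apply(d, 2, sd) / sqrt(n))
      tibble::tibble(
        comparison = paste(conditions[pairs[1, pi]], "vs", conditions[pairs[2, pi]]),
        time_s = time_s, t = tval, significant = abs(tval) > tcrit
      )
    }))
    attr(post, "adjusted_alpha") <- adj
  }
  structure(
    list(time_s = time_s, f = obs$f, threshold = thr, df1 = obs$df1,
         df2 = obs$df2, clusters = clusters, posthoc = post, n_perm = n_perm,
         seed = seed, variant = variant, alpha = alpha, n_subjects = n,
         k_conditions = k, conditions = conditions),
    class = "mrcp_spm"
  )
}

#' @export
print.mrcp_spm <- function(x, ...) {
  cat(sprintf(
    "<mrcp_spm> %s one-way ANOVA over %d time points (n = %d, k = %d)\n",
    x$variant, length(x$time_s), x$n_subjects, x$k_conditions
  ))
  cat(sprintf("  F threshold %.3f (df %d, %d; alpha %.3g), %d cluster(s)\n",
              x$threshold, x$df1, x$df2, x$alpha, nrow(x$clusters)))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' @method tidy mrcp_spm
#' @export
tidy.mrcp_spm <- function(x, ...) x$clusters

#' @method glance mrcp_spm
#' @export
glance.mrcp_spm <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, n_subjects = x$n_subjects,
    k_conditions = x$k_conditions, n_time = length(x$time_s),
    threshold = x$threshold, df1 = x$df1, df2 = x$df2,
    n_clusters = nrow(x$clusters),
    min_cluster_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_,
    n_perm = x$n_perm, alpha = x$alpha
  )
}
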