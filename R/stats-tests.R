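# Friedman omnibus and Wilcoxon signed-rank post-hoc tests, with exact
# small-sample inference by enumeration and asymptotic fallbacks.

perms_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                            sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE]))
  }
  out
}

friedman_table <- function(data, value, subject, condition) {
  if (is.matrix(data)) return(data)
  stopifnot(is.data.frame(data))
  wide <- tidyr::pivot_wider(
    dplyr::select(data, dplyr::all_of(c(subject, condition, value))),
    names_from = dplyr::all_of(condition), values_from = dplyr::all_of(value)
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide[[1]]
  m
}

# Conover's tie-corrected chi-square statistic from a matrix of within-row ranks
friedman_statistic <- function(r) {
  n <- nrow(r); k <- ncol(r)
  rj <- colSums(r)
  a <- sum(r^2)
  denom <- a - n * k * (k + 1)^2 / 4
  if (denom <= 0) return(0)
  (k - 1) * sum((rj - n * (k + 1) / 2)^2) / denom
}

#' Friedman rank test over a subjects-by-conditions table
#'
#' Mid-ranks within each subject, tie-corrected chi-square statistic.
#' For small tables (at most `exact_limit` within-subject rank arrangements)
#' the p-value is exact, computed by enumerating all `(k!)^n` equally likely
#' arrangements; otherwise it comes from the chi-square distribution with
#' `k - 1` degrees of freedom.
#'
#' @param data Numeric matrix (subjects in rows, conditions in columns) or a
#'   long data frame.
#' @param value,subject,condition Column names used when `data` is a data
#'   frame.
#' @param feature Optional label carried into the result.
#' @param method `"auto"` (default), `"exact"`, or `"asymptotic"`.
#' @param exact_limit Maximum number of arrangements enumerated. Default 5e5.
#' @return An object of class `mrcp_friedman` with `statistic`, `df`,
#'   `p_value`, `method`, `n_subjects`, `k_conditions`.
#' @examples
#' m <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3), 5, byrow = TRUE)
#' friedman_mrcp(m)$statistic # 10 for five identically ordered subjects
#' @export
friedman_mrcp <- function(data, value = "value", subject = "subject",
                          condition = "condition", feature = NA_character_,
                          method = c("auto", "exact", "asymptotic"),
                          exact_limit = 5e5) {
  method <- match.arg(method)
  m <- friedman_table(data, value, subject, condition)
  if (anyNA(m)) abort("missing cells in the subjects x conditions table")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("need at least 2 subjects and 2 conditions")
  r <- t(apply(m, 1, rank))
  stat <- friedman_statistic(r)
  n_arrange <- factorial(k)^n
  use_exact <- switch(method,
    exact = TRUE,
    asymptotic = FALSE,
    auto = n_arrange <= exact_limit
  )
  if (use_exact && n_arrange > exact_limit) {
    abort(sprintf("exact enumeration over %g arrangements exceeds `exact_limit`", n_arrange))
  }
  p_chisq <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  if (use_exact) {
    P <- perms_of(k)
    np <- nrow(P)
    combos <- as.matrix(expand.grid(rep(list(seq_len(np)), n)))
    a <- sum(r^2)
    denom <- a - n * k * (k + 1)^2 / 4
    if (denom <= 0) {
      p <- 1
    } else {
      rj <- matrix(0, nrow(combos), k)
      for (i in seq_len(n)) {
        ri_perm <- matrix(r[i, ][P], nrow = np, ncol = k)
        rj <- rj + ri_perm[combos[, i], , drop = FALSE]
      }
      stats_all <- (k - 1) * rowSums((rj - n * (k + 1) / 2)^2) / denom
      p <- mean(stats_all >= stat - 1e-9)
    }
  } else {
    p <- p_chisq
  }
  structure(
    list(statistic = stat, df = k - 1, p_value = p, p_chisq = p_chisq,
         method = if (use_exact) "exact" else "asymptotic",
         n_subjects = n, k_conditions = k, feature = feature),
    class = "mrcp_friedman"
  )
}

#' @export
print.mrcp_friedman <- function(x, ...) {
  cat(sprintf(
    "Friedman rank test%s: chi-square = %.4f, df = %d, p = %.4g (%s; n = %d, k = %d)\n",
    if (is.na(x$feature)) "" else paste0(" [", x$feature, "]"),
    x$statistic, x$df, x$p_value, x$method, x$n_subjects, x$k_conditions
  ))
  invisible(x)
}

#' @method tidy mrcp_friedman
#' @export
tidy.mrcp_friedman <- function(x, ...) {
  tibble::tibble(
    feature = x$feature, statistic = x$statistic, df = x$df,
    p_value = x$p_value, method = x$method,
    n_subjects = x$n_subjects, k_conditions = x$k_conditions
  )
}

#' @method glance mrcp_friedman
#' @export
glance.mrcp_friedman <- function(x, ...) tidy(x)

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped (their count is reported); the absolute
#' differences are mid-ranked. The statistic `W` is the smaller of the two
#' signed-rank sums. For `n <= exact_max_n` non-zero differences the
#' two-sided p-value is exact - the probability, over all `2^n` equally
#' likely sign assignments, that `min(W+, W-)` is at most the observed value
#' (computed by convolution over the rank generating function, which handles
#' ties exactly). For larger `n` a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x Numeric vector of differences, or the first sample if `y` given.
#' @param y Optional second paired sample (`differences = x - y`).
#' @param exact_max_n Largest `n` for exact inference. Default 25.
#' @param comparison Optional label carried into the result.
#' @return An object of class `mrcp_wilcoxon` with `statistic` (W),
#'   `w_plus`, `p_value`, `n_used`, `n_zeros`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(1.2, 0.8, 2.1, 0.4, 1.6))
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max_n = 25,
                                 comparison = NA_character_) {
  d <- if (is.null(y)) x else x - y
  n_zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("all paired differences are zero")
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0])
  total <- sum(rk)
  w <- min(w_plus, total - w_plus)
  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * rk))
    t2 <- sum(r2)
    counts <- numeric(t2 + 1)
    counts[1] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), counts[seq_len(t2 + 1 - r)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- as.integer(round(2 * w))
    p_low <- sum(probs[seq_len(w2 + 1)])
    p_high <- sum(probs[seq(w2 + (t2 - 2 * w2) + 1, t2 + 1)])
    p <- p_low + p_high
    if (2 * w2 == t2) p <- p - probs[w2 + 1]
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    z <- w_plus - mu
    corr <- 0.5 * sign(z)
    z <- (z - corr) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  structure(
    list(statistic = w, w_plus = w_plus, p_value = p, n_used = n,
         n_zeros = n_zeros, method = method, comparison = comparison),
    class = "mrcp_wilcoxon"
  )
}

#' @export
print.mrcp_wilcoxon <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank%s: W = %g, p = %.4g (%s; n = %d, %d zero(s) dropped)\n",
    if (is.na(x$comparison)) "" else paste0(" [", x$comparison, "]"),
    x$statistic, x$p_value, x$method, x$n_used, x$n_zeros
  ))
  invisible(x)
}

#' @method tidy mrcp_wilcoxon
#' @export
tidy.mrcp_wilcoxon <- function(x, ...) {
  tibble::tibble(
    comparison = x$comparison, statistic = x$statistic, w_plus = x$w_plus,
    p_value = x$p_value, n_used = x$n_used, n_zeros = x$n_zeros,
    method = x$method
  )
}

#' @method glance mrcp_wilcoxon
#' @export
glance.mrcp_wilcoxon <- function(x, ...) tidy(x)

#' Bonferroni-adjusted significance threshold
#'
#' Family alpha divided by the number of comparisons, reported at four
#' decimals (three pairwise comparisons at alpha 0.05 give 0.0167).
#'
#' @param alpha Family-wise significance level. Default 0.05.
#' @param m Number of comparisons (>= 1).
#' @return Adjusted threshold, rounded to 4 decimals.
#' @examples
#' bonferroni_alpha(0.05, 3)
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  round(alpha / m, 4)
}
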