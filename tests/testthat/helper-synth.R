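# Shared fixtures, all built in code.

quick_plan <- function(condition = "control", seed = 3) {
  simulate_session(plan_condition(condition, seed = seed), condition = condition)
}

# epoch set wrapping constructed traces (one per row)
trace_epochs <- function(x, rate = 1200, t0 = -4, trial_idx = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(trial_idx)) trial_idx <- seq_len(nrow(x)) - 1L
  time_s <- t0 + (seq_len(ncol(x)) - 1) / rate
  mrcpspeller:::new_epoch_set(x, time_s, rate, reference = "cue",
                              trial_idx = trial_idx)
}

# one EMG epoch with a gain-modulated burst planted at `onset` seconds
burst_epoch <- function(seed, rate = 1200, onset = 0.1, gain = 10,
                        burst_s = 2, sigma = 10, window = c(-4, 3)) {
  withr::with_seed(seed, {
    tt <- seq(window[1], window[2] - 1 / rate, by = 1 / rate)
    x <- rnorm(length(tt), 0, sigma)
    idx <- which(tt >= onset & tt < onset + burst_s)
    env <- rep(1, length(idx))
    nr <- round(0.05 * rate)
    env[seq_len(nr)] <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
    x[idx] <- x[idx] * (1 + (gain - 1) * env)
    trace_epochs(x, rate = rate, t0 = window[1])
  })
}

# independent brute-force oracles -------------------------------------------

# Friedman permutation p by direct recursion over per-subject orderings,
# with the tie-corrected chi-square computed from scratch.
oracle_friedman_stat <- function(m) {
  rk <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  col_sums <- colSums(rk)
  denom <- sum(rk^2) - n * k * (k + 1)^2 / 4
  if (denom <= 0) return(0)
  (k - 1) * sum((col_sums - n * (k + 1) / 2)^2) / denom
}

oracle_friedman_p <- function(m) {
  n <- nrow(m); k <- ncol(m)
  obs <- oracle_friedman_stat(m)
  perm_rows <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rows(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  count <- 0L; total <- 0L
  rec <- function(row, current) {
    if (row > n) {
      total <<- total + 1L
      if (oracle_friedman_stat(current) >= obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    for (p in perm_rows(m[row, ])) {
      current[row, ] <- p
      rec(row + 1L, current)
    }
  }
  rec(1L, m)
  count / total
}

# Wilcoxon signed-rank exact p over all 2^n sign assignments:
# P(min(W+, W-) <= observed min)
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- min(sum(rk[d > 0]), sum(rk[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stats_all <- apply(signs, 1, function(s) {
    wp <- sum(rk[s > 0])
    min(wp, sum(rk) - wp)
  })
  mean(stats_all <= w_obs + 1e-9)
}
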