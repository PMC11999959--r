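null_array <- function(n = 6, k = 3, nt = 50, sd = 1, seed = 1) {
  withr::with_seed(seed, array(rnorm(n * k * nt, sd = sd), c(n, k, nt)))
}

test_that("identical condition traces give F = 0 and no clusters", {
  n <- 6; nt <- 40
  base <- matrix(rnorm(n * nt), n, nt)
  arr <- array(0, c(n, 3, nt))
  for (j in 1:3) arr[, j, ] <- base
  s <- spm_anova(arr, seed = 1)
  expect_equal(max(s$f), 0)
  expect_equal(nrow(s$clusters), 0)
  expect_null(s$posthoc)
})

test_that("the pointwise F matches the classical ANOVA decomposition", {
  arr <- null_array(n = 7, k = 3, nt = 5, seed = 21)
  s_rm <- spm_anova(arr, variant = "rm", seed = 1)
  s_pool <- spm_anova(arr, variant = "pooled", seed = 1)
  d <- data.frame(
    y = as.vector(arr[, , 2]),
    s = factor(rep(1:7, times = 3)),
    c = factor(rep(1:3, each = 7))
  )
  f_rm <- summary(stats::aov(y ~ c + s, data = d))[[1]]["c", "F value"]
  f_pool <- summary(stats::aov(y ~ c, data = d))[[1]]["c", "F value"]
  expect_equal(s_rm$f[2], f_rm, tolerance = 1e-10)
  expect_equal(s_pool$f[2], f_pool, tolerance = 1e-10)
})

test_that("a planted condition offset is detected as a cluster covering its interval", {
  n <- 8; nt <- 100
  arr <- null_array(n = n, k = 3, nt = nt, sd = 0.05, seed = 31)
  tt <- seq(0, 1, length.out = nt)
  attr(arr, "time_s") <- tt
  lift <- tt >= 0.4 & tt <= 0.6
  arr[, 2, lift] <- arr[, 2, lift] + 1
  s <- spm_anova(arr, n_perm = 199, seed = 5)
  expect_gte(nrow(s$clusters), 1)
  main <- s$clusters[which.max(s$clusters$mass), ]
  expect_lte(main$start_s, 0.45)
  expect_gte(main$end_s, 0.55)
  expect_lte(main$p_value, 0.05)
  # significant omnibus triggers Bonferroni-corrected paired t curves
  expect_false(is.null(s$posthoc))
  expect_equal(attr(s$posthoc, "adjusted_alpha"), 0.0167)
  sig12 <- s$posthoc[s$posthoc$comparison == "1 vs 2", ]
  expect_true(all(sig12$significant[lift]))
})

test_that("cluster inference is reproducible given a seed", {
  arr <- null_array(seed = 41)
  arr[, 1, 10:20] <- arr[, 1, 10:20] + 1.2
  s1 <- spm_anova(arr, seed = 7)
  s2 <- spm_anova(arr, seed = 7)
  expect_identical(s1$clusters, s2$clusters)
})

test_that("unbalanced designs are rejected", {
  tr <- tibble::tibble(
    subject = c("a", "a", "b"), condition = c("x", "y", "x"),
    time_s = 0, value_uv = 1
  )
  expect_error(spm_anova(tr), "unbalanced")
})

test_that("grand averages collapse to mean and SD per condition", {
  tr <- tibble::tibble(
    condition = rep(c("control", "phrase"), each = 4),
    time_s = rep(c(0, 1), 4),
    value_uv = c(1, 2, 1, 2, 3, 5, 1, 1)
  )
  ga <- grand_average(tr)
  expect_equal(nrow(ga), 4)
  expect_equal(ga$sd_uv[ga$condition == "control"], c(0, 0))
  expect_equal(ga$mean_uv[ga$condition == "phrase" & ga$time_s == 0], 2)
  # +v and -v average to zero
  tr2 <- tibble::tibble(condition = "c", time_s = rep(0:1, 2),
                        value_uv = c(3, -1, -3, 1))
  expect_equal(grand_average(tr2)$mean_uv, c(0, 0))
})

test_that("subject mean traces carry one row per subject-condition-timepoint", {
  plan <- quick_plan()
  sub <- synth_subject(plan, success_prob = 1, seed = 2)
  ep <- demean_epochs(segment_epochs(sub$eeg, plan, channel = "Cz",
                                     window = c(-2, 1.5)))
  ep$subject <- "S01"; ep$condition <- "control"
  tr <- subject_mean_traces(list(ep))
  expect_equal(nrow(tr), ncol(ep$data))
  expect_equal(unique(tr$n_trials), 26)
})

test_that("autoplot returns ggplot objects", {
  arr <- null_array(seed = 51)
  s <- spm_anova(arr, seed = 3)
  expect_s3_class(autoplot(s), "ggplot")
  ep <- trace_epochs(matrix(rnorm(200), 2), rate = 100)
  expect_s3_class(autoplot(ep), "ggplot")
})
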