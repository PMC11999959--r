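aligned_from_trace <- function(x, rate = 1200) {
  ep <- trace_epochs(x, rate = rate, t0 = -2)
  ep$reference <- "pn"
  ep
}

test_that("slopes are exact on perfect lines and PP is max minus min", {
  rate <- 1200
  tt <- seq(-2, 1.5 - 1 / rate, by = 1 / rate)
  x <- ifelse(tt < 0, -10 * tt - 8, 8 * tt - 8) # V shape: slope -10 then +8
  f <- extract_features(aligned_from_trace(x), slope_windows(ns2 = c(-0.5, 0)))
  expect_equal(f$ns2_uv_s, -10)
  expect_equal(f$rebound_uv_s, 8)
  expect_equal(f$pn_uv, -8)
  expect_equal(f$pp_uv, max(x) - min(x))
  # a trace with min -8 and max +2 gives PP = 10
  y <- 2 * sin(2 * pi * (tt + 2) / 7)
  y[which.min(abs(tt))] <- -8
  expect_equal(extract_features(aligned_from_trace(y))$pp_uv, 10)
  # all-zero trace: every feature is zero
  z <- extract_features(aligned_from_trace(numeric(length(tt))))
  expect_true(all(as.numeric(z[, -1]) == 0))
})

test_that("slopes are translation-invariant and scale-equivariant", {
  rate <- 600
  tt <- seq(-2, 1.5 - 1 / rate, by = 1 / rate)
  withr::with_seed(8, x <- cumsum(rnorm(length(tt))) / 10)
  f0 <- extract_features(aligned_from_trace(x, rate))
  f_shift <- extract_features(aligned_from_trace(x + 42, rate))
  for (col in c("ns1_uv_s", "ns2_uv_s", "rebound_uv_s", "pp_uv")) {
    expect_equal(f_shift[[col]], f0[[col]], tolerance = 1e-9)
  }
  f_scaled <- extract_features(aligned_from_trace(3 * x, rate))
  for (col in c("pn_uv", "ns1_uv_s", "ns2_uv_s", "rebound_uv_s", "pp_uv")) {
    expect_equal(f_scaled[[col]], 3 * f0[[col]], tolerance = 1e-9)
  }
})

test_that("slope windows validate their ordering", {
  expect_error(slope_windows(ns1 = c(-0.4, -0.2)), "ordered")
  expect_error(slope_windows(ns2 = c(0, -1)), "increasing")
})

test_that("subject-condition means aggregate validated trials", {
  feats <- tibble::tibble(
    subject = rep(c("S01", "S02"), each = 2),
    condition = rep("control", 4),
    processing = "cz",
    trial_idx = c(0L, 1L, 0L, 1L),
    ns1_uv_s = c(-2, -4, -1, -3),
    pp_uv = c(10, 12, 9, 11)
  )
  m <- subject_condition_means(feats)
  expect_equal(nrow(m), 2)
  expect_equal(m$ns1_uv_s[m$subject == "S01"], -3)
  expect_equal(m$n_trials, c(2L, 2L))
  # a single trial per cell is its own mean
  one <- subject_condition_means(feats[1, ])
  expect_equal(one$ns1_uv_s, -2)
  # an empty cell is reported
  feats2 <- feats
  feats2$condition <- c("control", "control", "phrase", "phrase")
  expect_warning(subject_condition_means(feats2), "no validated trials")
})
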