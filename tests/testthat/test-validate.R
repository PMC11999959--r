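test_that("PN is the window minimum with the earliest-sample tie-break", {
  rate <- 100
  tt <- seq(-4, 5 - 1 / rate, by = 1 / rate)
  x <- numeric(length(tt))
  x[which.min(abs(tt + 0.1))] <- -8
  ep <- trace_epochs(x, rate = rate)
  pn <- detect_pn(ep)
  expect_equal(pn$pn_time_s, -0.1)
  expect_equal(pn$pn_amplitude_uv, -8)
  # two equal minima: the earlier one wins
  x2 <- numeric(length(tt))
  x2[which.min(abs(tt + 0.3))] <- -5
  x2[which.min(abs(tt - 0.2))] <- -5
  expect_equal(detect_pn(trace_epochs(x2, rate = rate))$pn_time_s, -0.3)
  # the search is restricted to the window
  x3 <- numeric(length(tt))
  x3[which.min(abs(tt + 3))] <- -50
  x3[which.min(abs(tt - 0.2))] <- -5
  expect_equal(detect_pn(trace_epochs(x3, rate = rate))$pn_time_s, 0.2)
})

# a constructed single-trial setting where all criteria hold
criteria_case <- function(pn_time = 0.2, emg = 0.1, ns1 = -3, ns2 = -9,
                          reb = 6, rate = 1200) {
  tt <- seq(-4, 5 - 1 / rate, by = 1 / rate)
  x <- -8 * exp(-((tt - pn_time)^2) / (2 * 0.2^2)) # smooth dip, strict minimum
  ep <- trace_epochs(x, rate = rate)
  pn <- detect_pn(ep)
  emg_tbl <- tibble::tibble(trial_idx = 0L, emg_onset_s = emg)
  feats <- tibble::tibble(trial_idx = 0L, pn_uv = -8, ns1_uv_s = ns1,
                          ns2_uv_s = ns2, rebound_uv_s = reb, pp_uv = 8)
  evaluate_criteria(ep, pn, emg_tbl, feats)
}

test_that("all four criteria combine into the success verdict", {
  ok <- criteria_case()
  expect_true(ok$success)
  expect_true(all(c(ok$c1, ok$c2, ok$c3)))
  expect_false(ok$rejected_early_pn)
  # an early PN is excluded even when everything else holds
  early <- criteria_case(pn_time = -1.2, emg = -1.1)
  expect_true(early$rejected_early_pn)
  expect_false(early$success)
  # EMG onset outside the half-second window fails criterion 1
  late_emg <- criteria_case(emg = 0.8)
  expect_false(late_emg$c1)
  expect_false(late_emg$success)
  # a missing EMG onset fails criterion 1
  no_emg <- criteria_case(emg = NA_real_)
  expect_false(no_emg$c1)
  expect_false(no_emg$success)
  # wrong slope signs fail criterion 2
  flat <- criteria_case(ns2 = 1)
  expect_false(flat$c2)
  expect_false(flat$success)
})

test_that("success rates reproduce the printed-table arithmetic", {
  mk <- function(n_succ, n_tot) {
    tibble::tibble(success = c(rep(TRUE, n_succ), rep(FALSE, n_tot - n_succ)))
  }
  expect_equal(success_rate(mk(25, 26))$success_rate_pct, 96)
  expect_equal(success_rate(mk(13, 26))$success_rate_pct, 50)
  expect_equal(success_rate(mk(26, 26))$success_rate_pct, 100)
  expect_equal(success_rate(mk(0, 26))$success_rate_pct, 0)
  # permutation invariance over trials
  a <- mk(17, 26)
  expect_equal(success_rate(a[sample(26), ]), success_rate(a))
  expect_error(success_rate(a[0, ]), "no trials")
})

test_that("re-alignment re-windows each trial around its own reference", {
  rate <- 1200
  plan <- quick_plan()
  tpl <- mrcp_template_params(smoothing_s = 0)
  sub <- synth_subject(plan, tpl, noise_params_off(), success_prob = 1, seed = 3)
  shifted <- dplyr::mutate(plan, onset_s = onset_s + 1)
  ep <- demean_epochs(segment_epochs(sub$eeg, shifted, channel = "Cz"))
  pn <- detect_pn(ep)
  al <- realign_epochs(ep, pn, reference = "pn")
  expect_equal(ncol(al$data), 4200) # 3.5 s at 1,200 Hz
  expect_equal(al$reference, "pn")
  # on noiseless planted data every trial minimum lands at time 0
  mins <- apply(al$data, 1, which.min)
  expect_true(all(al$time_s[mins] == 0))
  # cue reference reproduces a plain re-window at 0
  al_cue <- realign_epochs(ep, reference = "cue")
  mask <- ep$time_s >= -2 & ep$time_s < 1.5
  expect_equal(al_cue$data, ep$data[, mask])
  # a reference too close to the epoch edge drops the trial with a warning
  pn_bad <- pn
  pn_bad$pn_time_s[1] <- 4.2
  expect_warning(al2 <- realign_epochs(ep, pn_bad, reference = "pn"), "dropping")
  expect_equal(nrow(al2$data), 25)
  expect_error(realign_epochs(ep, pn[-1, ], reference = "pn"), "missing pn")
})
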