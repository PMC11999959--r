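test_that("generation is bit-reproducible given a seed", {
  plan <- quick_plan()
  a <- synth_subject(plan, success_prob = 0.6, seed = 7)
  b <- synth_subject(plan, success_prob = 0.6, seed = 7)
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(a$emg$data, b$emg$data)
  expect_identical(a$truth, b$truth)
  c <- synth_subject(plan, success_prob = 0.6, seed = 8)
  expect_false(identical(a$eeg$data, c$eeg$data))
})

test_that("success_prob bounds behave as planted", {
  plan <- quick_plan()
  none <- synth_subject(plan, success_prob = 0, seed = 1)
  expect_false(any(none$truth$mrcp_present))
  all_on <- synth_subject(plan, success_prob = 1, seed = 1)
  expect_true(all(all_on$truth$mrcp_present))
  expect_error(synth_subject(plan, success_prob = 1.2, seed = 1), "0, 1")
  expect_error(synth_subject(plan, success_prob = 0.5), "seed")
})

test_that("with noise off the planted Cz trace equals the template exactly", {
  plan <- quick_plan()
  tpl <- mrcp_template_params(smoothing_s = 0)
  sub <- synth_subject(plan, tpl, noise_params_off(), success_prob = 1, seed = 2)
  rate <- sub$eeg$rate
  tt_rec <- (seq_len(nrow(sub$eeg$data)) - 1) / rate
  for (i in c(1, 13, 26)) {
    pn <- sub$truth$true_pn_time_s[i]
    idx <- which(tt_rec >= pn - 2.5 & tt_rec <= pn + 1.5)
    expect_equal(sub$eeg$data[idx, "Cz"], mrcp_template(tt_rec[idx] - pn, tpl),
                 tolerance = 1e-12)
    # neighboring and outer channels carry the configured fractions
    expect_equal(sub$eeg$data[idx, "C3"], 0.5 * sub$eeg$data[idx, "Cz"])
    expect_equal(sub$eeg$data[idx, "Pz"], 0.25 * sub$eeg$data[idx, "Cz"])
    # Cz minimum in the trial window sits at the planted PN amplitude
    expect_equal(min(sub$eeg$data[idx, "Cz"]), tpl$pn_amplitude)
  }
})

test_that("planted times lie inside their trial windows", {
  plan <- quick_plan("phrase")
  sub <- synth_subject(plan, success_prob = 1, seed = 5)
  tr <- sub$truth
  expect_true(all(abs(tr$true_pn_time_s - tr$onset_s - 1) < 1))
  expect_true(all(abs(tr$true_emg_onset_s - tr$onset_s - 1) < 1))
})

test_that("the background spectrum falls with frequency and carries the 50 Hz line", {
  plan <- quick_plan()
  sub <- synth_subject(plan, noise = noise_params(line_amp = 10),
                       success_prob = 0, seed = 3)
  x <- sub$eeg$data[, "FP1"]
  sp <- stats::spec.pgram(stats::ts(x, frequency = sub$eeg$rate),
                          plot = FALSE, taper = 0)
  low <- mean(sp$spec[sp$freq > 0.5 & sp$freq < 2])
  mid <- mean(sp$spec[sp$freq > 10 & sp$freq < 20 & abs(sp$freq - 50) > 2])
  expect_gt(low, 5 * mid) # 1/f decay
  line <- mean(sp$spec[abs(sp$freq - 50) < 0.05])
  expect_gt(line, 100 * mid) # line peak stands out
})

test_that("a small cohort writes a complete, readable file set", {
  out <- withr::local_tempdir()
  man <- synth_cohort(out, n_subjects = 1, conditions = "control", seed = 4,
                      rate = 300)
  expect_equal(nrow(man), 1)
  expect_true(all(file.exists(c(man$eeg, man$emg, man$events, man$truth))))
  ev <- read_events(man$events)
  expect_equal(nrow(ev), 26)
  truth <- read_ground_truth(man$truth)
  expect_equal(attr(truth, "success_prob"), 0.67)
  rec <- read_edf(man$eeg)
  expect_identical(rec$labels,
                   c("FP1", "Fz", "FC1", "FC2", "C3", "Cz", "C4", "CP1", "CP2", "Pz"))
  expect_equal(rec$rate, 300)
})
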