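make_rec <- function(x, rate = 1200, labels = "Cz") {
  recording(matrix(x, ncol = length(labels)), rate = rate, labels = labels)
}

test_that("filters pass zero through and validate their bands", {
  z <- make_rec(numeric(2400))
  out <- apply_filter(z, filter_spec("notch"))
  expect_equal(max(abs(out$data)), 0)
  expect_error(apply_filter(make_rec(rnorm(100), rate = 60), filter_spec("notch")),
               "Nyquist")
  expect_error(filter_spec(band = c(3, 0.05)))
})

test_that("the notch removes a 50 Hz sine by at least 20 dB", {
  tt <- seq(0, 20, by = 1 / 1200)
  x <- sin(2 * pi * 50 * tt)
  y <- apply_filter(make_rec(x), filter_spec("notch"))$data[, 1]
  mid <- seq(round(length(tt) / 3), round(2 * length(tt) / 3))
  atten_db <- -20 * log10(max(abs(y[mid])))
  expect_gt(atten_db, 20)
})

test_that("the band-pass keeps a 1 Hz sine within 5%", {
  tt <- seq(0, 60, by = 1 / 1200)
  x <- sin(2 * pi * tt)
  y <- apply_filter(make_rec(x), filter_spec("bandpass"))$data[, 1]
  mid <- seq(round(length(tt) / 3), round(2 * length(tt) / 3))
  expect_lt(abs(max(abs(y[mid])) - 1), 0.05)
})

test_that("filtering is linear and zero-phase application leaves no group delay", {
  withr::with_seed(4, {
    x <- rnorm(6000); y <- rnorm(6000)
  })
  spec <- filter_spec("bandpass")
  fx <- apply_filter(make_rec(x), spec)$data[, 1]
  fy <- apply_filter(make_rec(y), spec)$data[, 1]
  fxy <- apply_filter(make_rec(2 * x - 3 * y), spec)$data[, 1]
  # the 0.05 Hz corner puts poles near the unit circle, so float error is
  # amplified well above machine precision; linearity holds to ~1e-7
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-6)
  # symmetric pulse keeps its peak sample under forward-backward filtering
  tt <- seq(0, 10, by = 1 / 1200)
  pulse <- exp(-((tt - 5)^2) / (2 * 0.4^2))
  fp <- apply_filter(make_rec(pulse), filter_spec("notch"))$data[, 1]
  expect_lte(abs(which.max(fp) - which.max(pulse)), 1)
})

test_that("epoching cuts 9-s windows (10,800 samples at 1,200 Hz) per event", {
  plan <- quick_plan()
  sub <- synth_subject(plan, success_prob = 0, seed = 1)
  ep <- segment_epochs(sub$eeg, plan, channel = "Cz")
  expect_equal(nrow(ep$data), 26)
  expect_equal(ncol(ep$data), 10800)
  expect_equal(ep$time_s[1], -4)
  expect_equal(ep$reference, "cue")
  # events too close to the recording edge are reported with their trial id
  bad <- dplyr::mutate(plan, onset_s = dplyr::if_else(trial_idx == 0, 2, onset_s))
  expect_error(segment_epochs(sub$eeg, bad, channel = "Cz"), "trial\\(s\\): 0")
  expect_error(segment_epochs(sub$eeg, plan, channel = "XX"), "not present")
})

test_that("demeaning zeroes every epoch mean and is idempotent", {
  ep <- trace_epochs(rbind(rep(3.7, 1000), sin(seq_len(1000) / 50) + 2))
  d1 <- demean_epochs(ep)
  expect_true(all(abs(rowMeans(d1$data)) < 1e-9))
  expect_equal(max(abs(d1$data[1, ])), 0)
  d2 <- demean_epochs(d1)
  expect_equal(d1$data, d2$data)
})

test_that("the large Laplacian is the center minus the ring mean", {
  n <- 100
  labs <- c("FP1", "Fz", "FC1", "FC2", "C3", "Cz", "C4", "CP1", "CP2", "Pz")
  x <- matrix(5, n, 10, dimnames = list(NULL, labs))
  rec <- recording(x, rate = 100)
  expect_equal(max(abs(large_laplacian(rec)$data)), 0) # common-mode rejection
  x2 <- matrix(0, n, 10, dimnames = list(NULL, labs))
  x2[, "Cz"] <- seq_len(n)
  expect_equal(large_laplacian(recording(x2, rate = 100))$data[, 1],
               as.numeric(seq_len(n)))
  x3 <- matrix(1, n, 10, dimnames = list(NULL, labs))
  x3[, "Cz"] <- 4
  expect_equal(unique(large_laplacian(recording(x3, rate = 100))$data[, 1]), 3)
  expect_error(large_laplacian(recording(x[, 1:4], rate = 100)), "missing channel")
})

test_that("Laplacian commutes with epoching and demeaning", {
  plan <- quick_plan()
  sub <- synth_subject(plan, success_prob = 1, seed = 6)
  ring <- c("Fz", "C3", "C4", "Pz")
  # route 1: Laplacian on the continuous data, then segment + demean
  e1 <- demean_epochs(segment_epochs(large_laplacian(sub$eeg), plan,
                                     channel = "Cz_lap"))
  # route 2: segment + demean each channel, then combine sample-wise
  ecz <- demean_epochs(segment_epochs(sub$eeg, plan, channel = "Cz"))$data
  ering <- lapply(ring, function(ch) {
    demean_epochs(segment_epochs(sub$eeg, plan, channel = ch))$data
  })
  e2 <- ecz - Reduce(`+`, ering) / length(ring)
  expect_equal(e1$data, e2, tolerance = 1e-9)
})
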