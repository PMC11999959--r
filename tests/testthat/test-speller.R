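test_that("layout has 36 distinct cells with A top-left and covers the phrase", {
  lay <- speller_layout()
  expect_equal(dim(lay$grid), c(6, 6))
  expect_equal(nrow(lay$cells), 36)
  expect_false(anyDuplicated(lay$cells$char) > 0)
  a <- lay$cells[lay$cells$char == "A", ]
  expect_equal(c(a$col, a$row), c(0, 0))
  phrase_chars <- unique(strsplit("HELLO IM FINE", "")[[1]])
  expect_true(all(phrase_chars %in% lay$cells$char))
})

test_that("condition phrases match the study design", {
  expect_equal(plan_condition("control"), strrep("O", 13))
  expect_equal(plan_condition("phrase"), "HELLO IM FINE")
  expect_identical(plan_condition("random", seed = 42),
                   plan_condition("random", seed = 42))
  expect_error(plan_condition("nonsense"))
  expect_error(plan_condition("random"), "seed")
})

test_that("the random phrase is always an anagram of the copy-spelling phrase", {
  ref <- sort(strsplit("HELLO IM FINE", "")[[1]])
  for (s in 1:20) {
    perm <- plan_condition("random", seed = s)
    expect_identical(sort(strsplit(perm, "")[[1]]), ref)
  }
})

test_that("a 13-character phrase yields 26 alternating column/row events", {
  ev <- simulate_session("HELLO IM FINE")
  expect_equal(nrow(ev), 26)
  expect_identical(ev$type, rep(c("column", "row"), 13))
  expect_identical(ev$trial_idx, 0:25)
  expect_true(all(diff(ev$onset_s) > 0))
})

test_that("event count is twice the phrase length and onsets are deterministic", {
  for (phrase in c("A", "OO", "HELLO IM FINE", "ZX0 8Q")) {
    ev1 <- simulate_session(phrase)
    ev2 <- simulate_session(phrase)
    expect_equal(nrow(ev1), 2 * nchar(phrase))
    expect_identical(ev1$onset_s, ev2$onset_s)
  }
})

test_that("identical characters always cue the same column and timing gaps respect the pause", {
  timing <- timing_spec()
  ev <- simulate_session(strrep("O", 13), timing = timing)
  col_onsets <- ev$onset_s[ev$type == "column"]
  # same letter -> same within-sweep offset, so constant inter-character stride
  expect_equal(length(unique(round(diff(col_onsets), 9))), 1)
  expect_true(all(diff(ev$onset_s) >= timing$pause_s))
})

test_that("characters outside the layout are rejected", {
  expect_error(simulate_session("HELLO!"), "not in speller layout")
})

test_that("timing invariants are enforced", {
  expect_error(timing_spec(midpoint_offset_s = 3), "midpoint")
  expect_error(timing_spec(dwell_s = 0))
})
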