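test_that("identical conditions give a zero Friedman statistic and p = 1", {
  m <- matrix(5, nrow = 4, ncol = 3)
  fr <- friedman_mrcp(m)
  expect_equal(fr$statistic, 0)
  expect_equal(fr$p_value, 1)
})

test_that("a consistent strict ordering across five subjects gives chi-square 10", {
  m <- matrix(rep(c(1, 2, 3), 5), nrow = 5, byrow = TRUE)
  fr <- friedman_mrcp(m)
  expect_equal(fr$statistic, 10)
  expect_equal(fr$df, 2)
})

test_that("the exact Friedman p matches brute-force enumeration to 1e-12", {
  withr::with_seed(11, {
    tables <- list(
      matrix(rnorm(12), 4, 3),
      matrix(sample(1:3, 12, replace = TRUE), 4, 3), # heavy ties
      matrix(c(1, 1, 2, 3, 2, 1, 2, 2, 2, 1, 3, 2), 4, 3)
    )
  })
  for (m in tables) {
    fr <- friedman_mrcp(m, method = "exact")
    expect_equal(fr$p_value, oracle_friedman_p(m), tolerance = 1e-12)
  }
})

test_that("the asymptotic Friedman path agrees with base R on tie-free data", {
  withr::with_seed(12, m <- matrix(rnorm(39), 13, 3))
  fr <- friedman_mrcp(m, method = "asymptotic")
  ft <- stats::friedman.test(m)
  expect_equal(fr$statistic, unname(ft$statistic), tolerance = 1e-12)
  expect_equal(fr$p_value, ft$p.value, tolerance = 1e-12)
  expect_error(friedman_mrcp(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "missing cells")
})

test_that("thirteen uniformly positive differences give the textbook exact p", {
  w <- wilcoxon_signed_rank(rep(1, 13) + (1:13) / 100)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 2 / 2^13, tolerance = 1e-15)
})

test_that("the exact signed-rank p matches 2^n enumeration to 1e-12", {
  withr::with_seed(13, {
    cases <- list(rnorm(6), c(1, -1, 2, -2, 3, 4), c(0.5, 0.5, -0.5, 1, 2, -2),
                  rnorm(5), c(2, 2, 2, -1))
  })
  for (d in cases) {
    w <- wilcoxon_signed_rank(d)
    expect_equal(w$p_value, oracle_wilcoxon_p(d), tolerance = 1e-12)
  }
})

test_that("the exact signed-rank p agrees with base R on tie-free pairs", {
  withr::with_seed(14, {
    x <- rnorm(12); y <- rnorm(12)
  })
  w <- wilcoxon_signed_rank(x, y)
  wb <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(w$p_value, wb$p.value, tolerance = 1e-12)
  # large-sample path matches the tie-corrected normal approximation
  withr::with_seed(15, {
    x2 <- rnorm(40); y2 <- rnorm(40)
  })
  w2 <- wilcoxon_signed_rank(x2, y2)
  wb2 <- stats::wilcox.test(x2, y2, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(w2$method, "normal")
  expect_equal(w2$p_value, wb2$p.value, tolerance = 1e-12)
})

test_that("symmetric differences sit at the distribution center with p = 1", {
  w <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))
  expect_equal(w$p_value, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
})

test_that("zero differences are dropped and counted", {
  w <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3))
  expect_equal(w$n_zeros, 2)
  expect_equal(w$n_used, 3)
})

test_that("the Bonferroni threshold matches the published adjustment", {
  expect_equal(bonferroni_alpha(0.05, 3), 0.0167)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 2), 0.005)
  expect_error(bonferroni_alpha(0.05, 0))
})

test_that("tidy and glance return one-row tibbles", {
  fr <- friedman_mrcp(matrix(rnorm(12), 4, 3), feature = "pp_uv")
  expect_s3_class(tidy(fr), "tbl_df")
  expect_equal(tidy(fr)$feature, "pp_uv")
  w <- wilcoxon_signed_rank(rnorm(8), comparison = "control vs phrase")
  expect_equal(nrow(tidy(w)), 1)
  expect_equal(tidy(w)$comparison, "control vs phrase")
})
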