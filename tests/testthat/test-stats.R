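test_that("summaries average images within replicate before pooling", {
  df <- data.frame(condition = "untreated",
                   replicate = rep(1:3, each = 2),
                   fraction_permeable = c(0.25, 0.35, 0.4, 0.4, 0.45, 0.55))
  s <- summarize_conditions(df, "fraction_permeable")
  expect_equal(s$mean, 0.4)                       # replicate means 0.3/0.4/0.5
  expect_equal(s$sem, sd(c(0.3, 0.4, 0.5)) / sqrt(3))
  expect_equal(s$sem, 0.1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$n_replicates, 3)
})

test_that("single-image replicates and identical replicates behave exactly", {
  df <- data.frame(condition = "c", replicate = 1:3,
                   fraction_permeable = c(0.2, 0.2, 0.2))
  s <- summarize_conditions(df, "fraction_permeable")
  expect_equal(s$mean, 0.2)
  expect_equal(s$sem, 0)
})

test_that("summaries are invariant to image order within replicates", {
  set.seed(5)
  df <- data.frame(condition = "c", replicate = rep(1:3, each = 4),
                   fraction_permeable = runif(12))
  s1 <- summarize_conditions(df, "fraction_permeable")
  s2 <- summarize_conditions(df[sample(12), ], "fraction_permeable")
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$sem, s2$sem)
})

test_that("the pooled t test reproduces hand-computed and degenerate cases", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- unpaired_t_test(a, b)
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  # identical samples
  r0 <- unpaired_t_test(a, a)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1); expect_equal(r0$stars, "ns")
  # zero pooled variance
  re <- unpaired_t_test(c(1, 1), c(1, 1))
  expect_equal(re$p, 1); expect_false(re$degenerate)
  rd <- unpaired_t_test(c(1, 1), c(2, 2))
  expect_true(rd$degenerate)
})

test_that("t statistic and p value match the closed-form oracle to 1e-10", {
  set.seed(11)
  for (i in 1:100) {
    a <- rnorm(sample(2:6, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -1, 1))
    r <- unpaired_t_test(a, b)
    o <- oracle_pooled_t(a, b)
    expect_lt(abs(r$t - o$t), 1e-10)
    expect_lt(abs(r$p - o$p), 1e-10)
    expect_equal(r$df, o$df)
  }
})

test_that("significance stars use strict threshold inequalities", {
  expect_equal(significance_stars(0.004), "**")
  expect_equal(significance_stars(0.0004), "***")
  expect_equal(significance_stars(0.04), "*")
  expect_equal(significance_stars(0.06), "ns")
  expect_equal(significance_stars(0.05), "ns")   # p < 0.05 is strict
  expect_equal(significance_stars(0.01), "*")
  expect_equal(significance_stars(0.001), "**")
})

test_that("percent change follows the decrease/increase convention", {
  expect_equal(percent_change(100, 54), -46)
  expect_equal(percent_change(100, 140), 40)
  expect_equal(percent_change(80, 80), 0)
  expect_error(percent_change(0, 10), "positive")
})
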