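# Brute-force transcription of the modified mean CoV: per-subject two-value
# standard deviations summed, divided by summed absolute pair means.
brute_cov <- function(x1, x2) {
  num <- 0; den <- 0
  for (i in seq_along(x1)) {
    num <- num + stats::sd(c(x1[i], x2[i]))
    den <- den + abs(mean(c(x1[i], x2[i])))
  }
  100 * num / den
}

test_that("modified CoV matches its hand-computed cases", {
  expect_equal(modified_cov(c(3, 5, 7), c(3, 5, 7)), 0)
  expect_equal(modified_cov(4, 6), 100 * (2 / sqrt(2)) / 5,
               tolerance = 1e-12)  # 28.28%
  expect_equal(modified_cov(c(10, 8), c(12, 8)),
               100 * (2 / sqrt(2)) / 19, tolerance = 1e-12)  # 7.44%
  expect_error(modified_cov(c(1, -1), c(-1, 1)), "zero")
})

test_that("modified CoV agrees with the brute-force formula on random tables", {
  set.seed(123)
  worst <- 0
  for (k in 1:1000) {
    n <- sample(1:12, 1)
    x1 <- stats::rnorm(n, sample(c(-5, 0.5, 10), 1), 2)
    x2 <- x1 + stats::rnorm(n, 0, 0.7)
    if (sum(abs((x1 + x2) / 2)) == 0) next
    worst <- max(worst, abs(modified_cov(x1, x2) - brute_cov(x1, x2)))
  }
  expect_lt(worst, 1e-12)
})

test_that("modified CoV is scale-invariant but not translation-invariant", {
  set.seed(5)
  x1 <- stats::rnorm(9, 10, 2)
  x2 <- x1 + stats::rnorm(9, 0, 0.5)
  base <- modified_cov(x1, x2)
  expect_equal(modified_cov(3 * x1, 3 * x2), base, tolerance = 1e-12)
  expect_equal(modified_cov(-x1, -x2), base, tolerance = 1e-12)
  # shifting the endpoint toward zero inflates the statistic: the
  # mid-ventricular twist pathology
  shifted <- modified_cov(x1 - 9.5, x2 - 9.5)
  expect_gt(shifted, 5 * base)
})

test_that("for one subject the statistic reduces to the per-subject CoV", {
  expect_equal(modified_cov(4, 6), 100 * stats::sd(c(4, 6)) / mean(c(4, 6)))
})

test_that("CoV of multiplicative repeat noise matches a Monte-Carlo oracle", {
  cv <- 0.05
  set.seed(77)
  # oracle: expectation of the statistic under x2 = x1 (1 + eps)
  oracle <- replicate(1000, {
    x1 <- stats::rnorm(9, 30, 5)
    modified_cov(x1, x1 * (1 + stats::rnorm(9, 0, cv)))
  })
  # analytic expectation of each subject's term: E|eps| / sqrt(2)
  analytic <- 100 * cv * sqrt(2 / pi) / sqrt(2)
  expect_equal(mean(oracle), analytic, tolerance = 0.1)
  # a single simulated cohort estimate falls inside the oracle spread
  x1 <- stats::rnorm(9, 30, 5)
  est <- modified_cov(x1, x1 * (1 + stats::rnorm(9, 0, cv)))
  expect_lt(abs(est - analytic), 5 * stats::sd(oracle))
})

test_that("Bland-Altman limits of agreement use mean +/- 2 SD", {
  ba <- bland_altman(c(0, 0), c(2, -2))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_high, 4 * sqrt(2), tolerance = 1e-12)  # 5.657
  expect_equal(ba$loa_low, -4 * sqrt(2), tolerance = 1e-12)
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(ba0), c(mean_diff = 0, sd_diff = 0, loa_low = 0,
                              loa_high = 0))
  # adding a constant to x2 shifts the mean difference, not its SD
  set.seed(2)
  x1 <- stats::rnorm(8); x2 <- x1 + stats::rnorm(8, 0, 0.3)
  b1 <- bland_altman(x1, x2)
  b2 <- bland_altman(x1, x2 + 1.5)
  expect_equal(b2$mean_diff, b1$mean_diff + 1.5, tolerance = 1e-12)
  expect_equal(b2$sd_diff, b1$sd_diff, tolerance = 1e-12)
  expect_error(bland_altman(1, 2), "2 pairs")
})

test_that("limits of agreement cover about 95% of Gaussian differences", {
  set.seed(31)
  d <- stats::rnorm(20000)
  ba <- bland_altman(rep(0, length(d)), d)
  coverage <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_equal(coverage, 2 * stats::pnorm(2) - 1, tolerance = 0.01)
})

test_that("the report applies the 20% rule inclusively and pairs conditions", {
  mk_table <- function(x1, x2, x_obs2 = x1) {
    rbind(
      data.frame(mouse = paste0("m", seq_along(x1)), group = "normal",
                 condition = "obs1_day1", endpoint = "ep", value = x1),
      data.frame(mouse = paste0("m", seq_along(x2)), group = "normal",
                 condition = "obs1_day2", endpoint = "ep", value = x2),
      data.frame(mouse = paste0("m", seq_along(x_obs2)), group = "normal",
                 condition = "obs2_day1", endpoint = "ep", value = x_obs2))
  }
  # identical days: CoV zero, flagged reproducible
  rep0 <- reproducibility_report(mk_table(c(4, 5, 6), c(4, 5, 6)))
  it <- rep0[rep0$comparison == "inter_test", ]
  expect_equal(it$cov, 0)
  expect_true(it$reproducible)
  # boundary: the rule is inclusive (CoV equal to the threshold passes)
  x1 <- c(10, 10); d <- 0.2 * 20 * sqrt(2) / 2
  tab20 <- mk_table(x1 - d / 2, x1 + d / 2)
  cov20 <- modified_cov(x1 - d / 2, x1 + d / 2)
  expect_equal(cov20, 20, tolerance = 1e-9)
  at <- reproducibility_report(tab20, "inter_test", cov_threshold = cov20)
  expect_true(at$reproducible)   # equality counts as reproducible
  just_below <- reproducibility_report(tab20, "inter_test",
                                       cov_threshold = cov20 * (1 - 1e-9))
  expect_false(just_below$reproducible)
  r21 <- reproducibility_report(mk_table(x1 - d / 2, x1 + d / 2 * 1.2))
  r21 <- r21[r21$comparison == "inter_test", ]
  expect_gt(r21$cov, 20)
  expect_false(r21$reproducible)
  # missing values drop the mouse with a message; < 2 mice -> NA, not dropped
  tab <- mk_table(c(4, 5, 6), c(4.1, NA, 6.2))
  expect_message(rep1 <- reproducibility_report(tab), "dropped 1 mice")
  expect_equal(rep1$n[rep1$comparison == "inter_test"], 2)
  tab2 <- mk_table(c(4, 5), c(4.1, NA))
  expect_message(rep2 <- reproducibility_report(tab2), "dropped")
  it2 <- rep2[rep2$comparison == "inter_test", ]
  expect_equal(it2$n, 1)
  expect_true(is.na(it2$cov))
})

test_that("subgroup reports restrict animals before the CoV sums", {
  tab <- rbind(
    data.frame(mouse = c("a", "b"), group = "normal",
               condition = "obs1_day1", endpoint = "ep", value = c(10, 12)),
    data.frame(mouse = c("a", "b"), group = "normal",
               condition = "obs1_day2", endpoint = "ep", value = c(11, 12)),
    data.frame(mouse = c("c", "d"), group = "obese",
               condition = "obs1_day1", endpoint = "ep", value = c(20, 22)),
    data.frame(mouse = c("c", "d"), group = "obese",
               condition = "obs1_day2", endpoint = "ep", value = c(26, 22)))
  rep_all <- reproducibility_report(tab, "inter_test",
                                    subgroups = c("normal", "obese"))
  cov_norm <- rep_all$cov[rep_all$scope == "normal"]
  cov_obese <- rep_all$cov[rep_all$scope == "obese"]
  expect_equal(cov_norm, modified_cov(c(10, 12), c(11, 12)))
  expect_equal(cov_obese, modified_cov(c(20, 22), c(26, 22)))
  expect_gt(cov_obese, cov_norm)
})
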