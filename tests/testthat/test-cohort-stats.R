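test_that("adjudication follows the mean / adjudicated rule", {
  df <- tibble::tibble(id = c("a", "b", "c"),
                       obs1_mm = c(2.0, 2.0, 1.5),
                       obs2_mm = c(2.4, 3.5, 1.5),
                       obs3_mm = c(NA, 2.0, NA))
  out <- adjudicate(df)
  expect_equal(out$final_mm, c(2.2, 2.0, 1.5))
  expect_equal(out$flagged, c(FALSE, TRUE, FALSE))

  # flagged case without adjudicated value errors, naming the patient
  df$obs3_mm <- NA_real_
  expect_error(adjudicate(df), "missing adjudication.*b")

  # alternative mode keeps the two-observer mean even when flagged
  out2 <- adjudicate(df, flagged_value = "mean")
  expect_equal(out2$final_mm[2], 2.75)
  expect_true(out2$flagged[2])

  # exactly at the threshold is not flagged (rule is "more than")
  at <- adjudicate(tibble::tibble(obs1_mm = 2, obs2_mm = 3))
  expect_false(at$flagged)
  expect_equal(at$final_mm, 2.5)
})

test_that("cohort summary statistics match hand arithmetic", {
  df <- tibble::tibble(obs1_mm = c(1, -2, 3), obs2_mm = c(1, -2, 3))
  s <- summarize_cohort(df, subgroup_tests = FALSE, icc = FALSE,
                        normality = FALSE)
  expect_equal(s$mean_abs, 2)
  expect_equal(s$mean_signed, 2 / 3)
  expect_equal(s$sd_signed, sd(c(1, -2, 3)))
  expect_equal(s$min_abs, 1)
  expect_equal(s$max_abs, 3)
  expect_equal(s$n_adjudicated, 0)

  z <- tibble::tibble(obs1_mm = rep(0, 4), obs2_mm = rep(0, 4))
  sz <- summarize_cohort(z, subgroup_tests = FALSE, icc = FALSE,
                         normality = FALSE)
  expect_equal(sz$mean_abs, 0)
  expect_equal(sz$sd_abs, 0)
  expect_equal(sz$mean_signed, 0)

  expect_error(summarize_cohort(df[1, ]), "insufficient data")
})

test_that("cohort summary is invariant to record order", {
  co <- simulate_cohort(n_patients = 40, seed = 9)
  s1 <- glance(summarize_cohort(co))
  s2 <- glance(summarize_cohort(co[sample(nrow(co)), ]))
  expect_equal(s1, s2)
})

test_that("simulated cohort mean absolute difference sits in the folded-normal band", {
  # population E|X| for X ~ N(1.02, 2.98) via the closed form, checked
  # against numerical integration in its own test; sampling band at n=65
  mu_abs <- folded_normal_mean(1.02, 2.98)
  var_abs <- 1.02^2 + 2.98^2 - mu_abs^2
  se <- sqrt(var_abs / 65)
  co <- simulate_cohort(n_patients = 65, observer_noise_sd = 0, seed = 21)
  s <- summarize_cohort(co, subgroup_tests = FALSE, icc = FALSE,
                        normality = FALSE)
  expect_lt(abs(s$mean_abs - mu_abs), 1.96 * se)
})

test_that("subgroup t-test handles standard and degenerate cases", {
  same <- subgroup_t_test(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  sep <- subgroup_t_test(c(0, 0, 0, 0, 10, 10, 10, 10),
                         rep(c("a", "b"), each = 4))
  expect_lt(sep$p, 1e-10)

  expect_error(subgroup_t_test(c(1, 2, 3), c("a", "a", "b")),
               "insufficient data")
  expect_error(subgroup_t_test(1:4, rep("a", 4)), "2 levels")

  # Student variant reproduces stats::t.test with pooled variance
  x <- c(1.2, 0.8, 1.9, 2.2, 1.1)
  y <- c(2.4, 2.9, 1.8, 2.2)
  g <- rep(c("a", "b"), c(5, 4))
  ours <- subgroup_t_test(c(x, y), g, var_equal = TRUE)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
})

test_that("subgroup t-test holds its type-I error under the null", {
  withr::local_seed(5)
  reps <- 2000
  rej <- mean(vapply(seq_len(reps), function(i) {
    v <- rnorm(60)
    subgroup_t_test(v, rep(c("a", "b"), each = 30))$p < 0.05
  }, logical(1)))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("normality check behaves under null, alternative and degeneracy", {
  withr::local_seed(8)
  # under the null the Lilliefors test rejects at ~alpha
  rej <- mean(vapply(1:400, function(i) {
    ks_normality(rnorm(100))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)

  # heavy skew is detected essentially always at n = 1000
  pow <- mean(vapply(1:40, function(i) {
    ks_normality(rexp(1000))$p < 0.05
  }, logical(1)))
  expect_gte(pow, 0.95)

  expect_warning(out <- ks_normality(rep(1, 10)), "constant")
  expect_equal(out$p, 0)
  expect_error(ks_normality(c(1, 2, 3)), "insufficient data")

  # naive variant is the plain KS test with estimated parameters
  x <- rnorm(50)
  naive <- ks_normality(x, lilliefors = FALSE)
  ref <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  expect_equal(naive$statistic, unname(ref$statistic))
})

test_that("ICC(2,1) matches its closed-form and boundary behaviour", {
  x <- c(1.3, 2.8, 0.2, 4.1, 2.2, 3.3, 1.9)
  perfect <- icc_two_observers(cbind(x, x))
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$ci_low, 1)

  withr::local_seed(12)
  # independent columns: ICC near 0
  nullc <- icc_two_observers(cbind(rnorm(1000), rnorm(1000)))
  expect_lt(abs(nullc$icc), 0.1)

  # subject SD 1.81 with observer noise SD 0.1: variance-ratio regime
  subj <- rnorm(1000, 2.57, 1.81)
  obs <- cbind(subj + rnorm(1000, 0, 0.1), subj + rnorm(1000, 0, 0.1))
  r <- icc_two_observers(obs)
  closed <- 1.81^2 / (1.81^2 + 0.1^2)
  expect_gte(r$icc, 0.99)
  expect_lt(abs(r$icc - closed), 0.01)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)

  expect_error(icc_two_observers(cbind(c(1, 2, NA, 4, 5), 1:5)), "missing")
  expect_error(icc_two_observers(cbind(1:4, 1:4)), "insufficient")
  expect_error(icc_two_observers(matrix(1, 6, 3)), "2 columns")
})

test_that("sample size for a mean reproduces the ceiling formula", {
  expect_identical(sample_size_mean(1.95, 0.5, 0.05), 59L)
  expect_identical(sample_size_mean(2.0, 0.5, 0.05), 62L)
  z <- qnorm(0.975)
  expect_identical(sample_size_mean(3, z * 3, 0.05), 1L)

  # monotone: non-increasing in half-width, non-decreasing in sd
  hw <- seq(0.2, 2, by = 0.2)
  expect_true(all(diff(vapply(hw, function(h)
    sample_size_mean(1.95, h), 1L)) <= 0))
  sds <- seq(0.5, 4, by = 0.25)
  expect_true(all(diff(vapply(sds, function(s)
    sample_size_mean(s, 0.5), 1L)) >= 0))

  expect_error(sample_size_mean(0, 0.5), "sd")
  expect_error(sample_size_mean(1, 0), "half_width")
  expect_error(sample_size_mean(1, 1, 1.5), "alpha")
})

test_that("folded normal mean matches numerical integration", {
  cases <- rbind(c(0, 1), c(1.02, 2.98), c(2.57, 1.81), c(-3, 0.5),
                 c(0.2, 4))
  for (i in seq_len(nrow(cases))) {
    mu <- cases[i, 1]; sg <- cases[i, 2]
    num <- integrate(function(x) abs(x) * dnorm(x, mu, sg), -Inf, Inf,
                     rel.tol = 1e-12)$value
    expect_equal(folded_normal_mean(mu, sg), num, tolerance = 1e-9)
  }
  expect_equal(folded_normal_mean(0, 2), 2 * sqrt(2 / pi))
  expect_equal(folded_normal_mean(-4.2, 0), 4.2)
  expect_error(folded_normal_mean(1, -1), "sigma")
})

test_that("glance/tidy/print/autoplot expose the cohort summary", {
  co <- simulate_cohort(n_patients = 30, seed = 14)
  s <- summarize_cohort(co)
  g <- glance(s)
  expect_equal(g$n, 30)
  expect_true(g$icc > 0.99)
  td <- tidy(s)
  expect_true(all(c("factor", "measure", "p") %in% names(td)))
  expect_setequal(unique(td$factor), c("age_group", "sex", "malunion_side"))

  tab <- format_cohort_table(s)
  expect_true(any(grepl("Malunion side", tab)))
  expect_true(any(grepl("ICC", tab)))

  pl <- ggplot2::autoplot(s)
  expect_s3_class(pl, "ggplot")
})
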