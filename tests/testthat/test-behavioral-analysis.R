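test_that("exclusion filters remove exactly the constructed violations", {
  resp <- tiny_responses()
  ppl <- tiny_participants()
  out <- apply_exclusions(resp, ppl, experiment = 1)
  expect_equal(out$ledger$n_excluded[out$ledger$criterion == "all_same_responses"], 1L)
  expect_equal(out$participants$participant_id, "ok")

  # probe accuracy: 10/12 excluded, 11/12 retained
  probe_fix <- function(n_ok) {
    tibble::tibble(participant_id = "p", kind = c(rep("testing", 20), rep("probe", 12)),
                   task = "judgment",
                   x_value = c(rep(c(1, 2), 10), rep(NA, 12)),
                   response = c(rep(c(0L, 1L), 10), rep(NA, 12)),
                   probe_correct = c(rep(NA, 20), rep(TRUE, n_ok), rep(FALSE, 12 - n_ok)))
  }
  ppl1 <- tiny_participants()[1, ] |> dplyr::mutate(participant_id = "p")
  expect_equal(nrow(apply_exclusions(probe_fix(10), ppl1, 1)$participants), 0)
  expect_equal(nrow(apply_exclusions(probe_fix(11), ppl1, 1)$participants), 1)

  # flags dominate, in order
  ppl_bad <- dplyr::mutate(tiny_participants(), headphone_pass = c(FALSE, TRUE))
  out2 <- apply_exclusions(resp, ppl_bad, 1)
  expect_equal(out2$excluded$criterion, c("headphone_fail", "all_same_responses"))

  expect_error(apply_exclusions(resp[, -5], ppl, 1), "must contain")
})

test_that("the detection-task bias rule applies only to experiments 3-4", {
  biased <- tibble::tibble(
    participant_id = "p", kind = c(rep("testing", 40), rep("probe", 12)),
    task = c(rep(c("music", "speech"), each = 20), rep("music", 12)),
    x_value = rep(1:2, length.out = 52),
    response = c(rep(c(1L, 1L, 1L, 1L, 0L), 4),   # music task: 80% rate
                 rep(c(0L, 1L), 10),              # speech task: 50% rate
                 rep(NA, 12)),
    probe_correct = c(rep(NA, 40), rep(TRUE, 12))
  )
  ppl <- dplyr::mutate(tiny_participants()[1, ], participant_id = "p")
  out3 <- apply_exclusions(biased, ppl, experiment = 3)
  expect_equal(out3$excluded$criterion, "response_bias") # 80% music-task rate
  out1 <- apply_exclusions(biased, ppl, experiment = 1)
  expect_true(is.na(out1$excluded$criterion))
})

test_that("exclusion accounting reconciles recruitment with inclusions", {
  expect_equal(reconcile_exclusion_counts(100, integer(0)), 100)
  expect_equal(reconcile_exclusion_counts(10, c(3, 2)), 5)
  expect_error(reconcile_exclusion_counts(10, c(-1, 2)), "nonnegative")
  expect_error(reconcile_exclusion_counts(3, c(2, 2)), "exceed")
})

test_that("the linear fit matches the closed-form least-squares solution", {
  fit <- fit_linear(c(1, 2, 3), c(0, 1, 1))
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, -1 / 3)
  oracle <- lm(y ~ x, data = data.frame(x = c(1, 2, 3), y = c(0, 1, 1)))
  expect_equal(fit$slope, unname(coef(oracle)[2]))
  expect_equal(fit$intercept, unname(coef(oracle)[1]))
  expect_equal(fit$r_squared, summary(oracle)$r.squared)
  # zero-variance convention
  flat <- fit_linear(c(1, 2, 3), c(1, 1, 1))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(fit_linear(c(1, 1), c(0, 1)), "distinct")
})

test_that("trial-level and level-mean slopes agree under balanced designs", {
  set.seed(9)
  x <- rep(1:6, each = 25)
  y <- rbinom(length(x), 1, 0.3 + 0.08 * x)
  trial <- fit_linear(x, y)
  means <- tapply(y, x, mean)
  level <- fit_linear(as.numeric(names(means)), as.numeric(means))
  expect_lt(abs(trial$slope - level$slope), 1e-10)
})

test_that("the bounded logistic fit recovers noiseless parameters", {
  x <- seq(0.6, 6, length.out = 10)
  y <- 1 / (1 + exp(-3 * (x - 2)))
  fit <- fit_logistic(x, y, bounds = c(0.6, 6))
  expect_lt(abs(fit$a - 2), 1e-3)
  expect_lt(abs(fit$slope - 3), 1e-3)
  expect_gt(fit$r_squared, 0.9999)
  # flat data: zero slope, zero R^2
  flat <- fit_logistic(x, rep(0.5, 10))
  expect_equal(flat$r_squared, 0)
  # the midpoint respects its bounds even when data pull it outside
  steep <- fit_logistic(x, rep(c(0, 1), c(1, 9)), bounds = c(0.6, 6))
  expect_gte(steep$a, 0.6)
  expect_lte(steep$a, 6)
  expect_error(fit_logistic(c(1, 2), c(0, 1)), "distinct")
})

test_that("model comparison returns the paired mean R-squared difference", {
  fits <- tibble::tibble(r_squared = c(0.5, 0.6), log_r_squared = c(0.5, 0.6))
  expect_equal(compare_models(fits), 0)
  fits$log_r_squared <- fits$r_squared - 0.19
  expect_equal(compare_models(fits), 0.19)
})

test_that("linear data give the linear model the goodness-of-fit advantage", {
  sim <- simulate_experiment(1, population_spec(n = 100), seed = 71)
  fits <- fit_psychometric(sim$responses)
  expect_equal(nrow(fits), 100)
  expect_gt(compare_models(fits), 0)
})

test_that("slope inference follows the definitional formulas", {
  tt <- one_sample_slope_test(c(0.1, 0.2, 0.3))
  expect_equal(tt$t, 0.2 / (0.1 / sqrt(3)))
  expect_equal(tt$df, 2)
  expect_equal(tt$d, 2)
  sym <- one_sample_slope_test(c(-0.2, -0.1, 0.1, 0.2))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  expect_error(one_sample_slope_test(c(1, 1)), "variance")
})

test_that("correlation inference reports both with- and without-outlier fits", {
  cc <- correlate_slopes(c(1, 2, 3), c(2, 1, 3))
  expect_equal(cc$r, 0.5)
  expect_equal(cc$df, 1)
  perfect <- correlate_slopes(1:5, 1:5 * 2)
  expect_equal(perfect$r, 1)
  # a gross outlier is flagged and removed in the second estimate
  set.seed(4)
  x <- rnorm(60)
  y <- 0.3 * x + rnorm(60, sd = 0.3)
  y[1] <- 25
  cc2 <- correlate_slopes(x, y)
  expect_equal(cc2$n_outliers, 1)
  expect_equal(cc2$outliers, 1L)
  expect_equal(cc2$df_no_outlier, 57)
  expect_gt(abs(cc2$r_no_outlier), abs(cc2$r))
  expect_error(correlate_slopes(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("the split-group Welch test matches hand computation", {
  w <- split_group_welch(c(1, 1, 1, -1, -1, -1), c(1, 2, 3, 0, 1, 2))
  expect_equal(w$t, (2 - 1) / sqrt(1 / 3 + 1 / 3))
  expect_equal(w$df, 4)
  expect_equal(w$d, 1)
  same <- split_group_welch(c(1, 1, -1, -1), c(3, 5, 3, 5))
  expect_equal(same$t, 0)
  expect_error(split_group_welch(c(1, 1), c(1, 2)), "empty")
})

test_that("t, r and Welch statistics match stats-package oracles on random data", {
  set.seed(2024)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    tt <- one_sample_slope_test(a)
    or <- t.test(a)
    expect_equal(tt$t, unname(or$statistic))
    expect_equal(tt$p, or$p.value)
    cc <- correlate_slopes(a, b)
    oc <- cor.test(a, b)
    expect_equal(cc$r, unname(oc$estimate))
    expect_equal(cc$p, oc$p.value)
    s <- rnorm(n)
    if (any(s > 0) && any(s <= 0) && sum(s > 0) > 1 && sum(s <= 0) > 1) {
      w <- split_group_welch(s, b)
      ow <- t.test(b[s > 0], b[s <= 0])
      expect_equal(w$t, unname(ow$statistic))
      expect_equal(w$df, unname(ow$parameter))
      expect_equal(w$p, ow$p.value)
    }
  }
})

test_that("noncentral-t power analysis is exact and monotone", {
  n1 <- power_required_n(0.68, alpha = 0.05, power = 0.8)
  expect_gte(power_one_sample_t(n1, 0.68, 0.05), 0.8)
  expect_lt(power_one_sample_t(n1 - 1, 0.68, 0.05), 0.8)
  # monte-carlo oracle at the returned n
  set.seed(7)
  mc <- mean(replicate(100000, {
    x <- rnorm(n1, 0.68, 1)
    abs(mean(x) / (sd(x) / sqrt(n1))) > qt(0.975, n1 - 1)
  }))
  expect_equal(mc, power_one_sample_t(n1, 0.68, 0.05), tolerance = 0.01)
  # monotonicity
  expect_lte(power_required_n(0.8, 0.05, 0.8), power_required_n(0.6, 0.05, 0.8))
  expect_lte(power_required_n(0.68, 0.05, 0.8), power_required_n(0.68, 0.01, 0.8))
  expect_lte(power_required_n(0.68, 0.05, 0.8), power_required_n(0.68, 0.05, 0.9))
  expect_error(power_required_n(-1), "positive")
})

test_that("summary effect sizes follow their definitions", {
  expect_equal(round(cohens_d_from_summary(81.58, 71.39, 20.62), 2), 0.49)
  expect_equal(cohens_d_from_summary(5, 5, 2), 0)
  expect_equal(cohens_d_from_summary(2, 1, 0.5), 2)
  expect_error(cohens_d_from_summary(1, 2, 0), "positive")
})

test_that("grouped designs yield one slope per participant-group pair", {
  sim <- simulate_experiment(2, population_spec(n = 6), seed = 81)
  fits <- fit_psychometric(sim$responses, group_by = "m_hz")
  expect_equal(nrow(fits), 6 * 3)
  expect_setequal(unique(fits$m_hz), c(1, 2.5, 4))
})

test_that("whole-experiment reports assemble and tidy cleanly", {
  sim <- simulate_experiment(3, population_spec(n = 8, alpha_sd = 0.05), seed = 91)
  rep3 <- analyze_experiment(sim$responses, sim$participants, 3)
  expect_s3_class(rep3, "stats_report")
  expect_named(rep3$groups, c("music", "speech"))
  # inclusion accounting is internally consistent
  expect_equal(rep3$n_included, 8 - sum(rep3$exclusions$n_excluded))
  td <- tidy(rep3)
  expect_true(all(c("group", "statistic_name", "estimate", "p.value") %in% names(td)))
  gl <- glance(rep3)
  expect_equal(gl$experiment, 3)
})
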