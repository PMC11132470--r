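test_that("population sampling matches the requested joint distribution", {
  spec0 <- population_spec(n = 5000, rho = 0)
  pop0 <- sample_population(spec0, seed = 101)
  expect_lt(abs(cor(pop0$beta, pop0$msi)), 0.05)
  expect_true(all(pop0$msi >= 18 & pop0$msi <= 126))
  expect_true(all(pop0$lapse >= 0 & pop0$lapse < 0.5))

  spec9 <- population_spec(n = 5000, rho = 0.9)
  pop9 <- sample_population(spec9, seed = 102)
  expect_gt(cor(pop9$beta, pop9$msi), 0.85)
  expect_lt(cor(pop9$beta, pop9$msi), 0.95)

  # degenerate SD pins the covariate at its mean
  pop_c <- sample_population(population_spec(n = 50, msi_sd = 0), seed = 103)
  expect_true(all(pop_c$msi == 81.58))

  expect_error(population_spec(rho = 1.2), "\\[-1, 1\\]")
  expect_error(population_spec(lapse_max = 0.6), "0.5")
  expect_error(population_spec(frac_all_same = 0.7, frac_biased = 0.7), "at most 1")
})

test_that("archetype fractions are honoured", {
  spec <- population_spec(n = 100, frac_all_same = 0.1, frac_probe_fail = 0.05,
                          frac_biased = 0.15)
  pop <- sample_population(spec, seed = 8)
  expect_equal(sum(pop$archetype == "all_same"), 10)
  expect_equal(sum(pop$archetype == "probe_fail"), 5)
  expect_equal(sum(pop$archetype == "biased"), 15)
})

test_that("the response model composes linearity, clipping and lapses", {
  prof <- list(alpha = 0.5, beta = 0, lapse = 0)
  expect_equal(response_probability(prof, c(-5, 0, 5)), rep(0.5, 3))
  prof <- list(alpha = 0.5, beta = 0.1, lapse = 0)
  expect_equal(response_probability(prof, 2, x_ref = 0), 0.7)
  prof <- list(alpha = 1, beta = 1, lapse = 0.2)
  expect_equal(response_probability(prof, 5, x_ref = 0), 0.9) # clipped then mixed
})

test_that("simulated responses honour archetypes and are seed-deterministic", {
  sched <- build_schedule(condition_grid(1), seed = 31)
  pop <- sample_population(population_spec(n = 1), seed = 32)

  const <- dplyr::mutate(pop, archetype = "all_same")
  r_const <- simulate_responses(const[1, ], sched, seed = 33)
  expect_equal(unique(r_const$response[r_const$kind == "testing"]), 1L)

  ok <- dplyr::mutate(pop, probe_failure_rate = 0)
  r_ok <- simulate_responses(ok[1, ], sched, seed = 34)
  expect_true(all(r_ok$probe_correct[r_ok$kind == "probe"]))

  fail <- dplyr::mutate(pop, probe_failure_rate = 1)
  r_fail <- simulate_responses(fail[1, ], sched, seed = 35)
  expect_false(any(r_fail$probe_correct[r_fail$kind == "probe"]))

  expect_identical(r_ok, simulate_responses(ok[1, ], sched, seed = 34))
})

test_that("the generative slope is recovered by the linear fit", {
  sched <- build_schedule(condition_grid(1), seed = 41)
  prof <- tibble::tibble(participant_id = "p", beta = 0.1, alpha = 0.5,
                         lapse = 0, archetype = "compliant",
                         probe_failure_rate = 0, bias_target = NA)
  r <- simulate_responses(prof, sched, seed = 42)
  test <- dplyr::filter(r, kind == "testing")
  fit <- fit_linear(test$x_value, test$response)
  se <- summary(lm(test$response ~ test$x_value))$coefficients[2, 2]
  expect_lt(abs(fit$slope - 0.1), 3 * se)
})

test_that("mean fitted slope converges to the true slope without lapses", {
  # ~10x the usual trial count per level, many participants, lapse-free
  spec <- population_spec(n = 48, beta_mean = 0.08, beta_sd = 0, lapse_max = 0,
                          alpha_sd = 0)
  x <- rep(condition_grid(1)$m_hz, each = 300)
  sims <- simulate_slope_experiments(spec, x, n_reps = 20, seed = 55)
  expect_lt(abs(mean(sims$mean_slope) - 0.08) / 0.08, 0.05)
})

test_that("the calibration driver's closed-form slope is the OLS slope", {
  set.seed(12)
  x <- rep(condition_grid(1)$m_hz, each = 30)
  y <- rbinom(length(x), 1, 0.5)
  xc <- x - mean(x)
  closed <- sum(xc * y) / sum(xc^2)
  expect_equal(closed, fit_linear(x, y)$slope)
})
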