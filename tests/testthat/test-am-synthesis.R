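test_that("1/f weighting divides pointwise and compensation undoes it", {
  curve <- spectrum_curve(c(0.5, 1, 2, 4), c(1, 1, 1, 1))
  w <- apply_one_over_f(curve)
  expect_equal(w$power, c(2, 1, 0.5, 0.25))
  expect_equal(compensate_one_over_f(w)$power, curve$power)
  # designed peak survives the weighting round trip on a dense grid
  f <- seq(0.01, 12, by = 0.01)
  raw <- lognormal_am_spectrum(am_params(2, 0.35), f)
  expect_equal(am_peak(apply_one_over_f(raw), compensate = TRUE),
               am_peak(raw, compensate = FALSE))
})

test_that("spectrum grids exclude DC and malformed curves are rejected", {
  expect_error(spectrum_curve(c(0, 1), c(1, 1)), "above 0")
  expect_error(spectrum_curve(c(2, 1), c(1, 1)), "increasing")
  expect_error(spectrum_curve(1, -1), "nonnegative")
})

test_that("envelope synthesis honours its normalization, length and seed contracts", {
  f <- seq(0.25, 64, by = 0.25)
  curve <- apply_one_over_f(lognormal_am_spectrum(am_params(2, 0.35), f))
  e <- spectrum_to_envelope(curve, duration = 4, env_rate = 1000, seed = 11)
  expect_equal(length(e$samples), 4000)
  expect_equal(min(e$samples), 0)
  expect_equal(max(e$samples), 1)
  # determinism
  e2 <- spectrum_to_envelope(curve, duration = 4, env_rate = 1000, seed = 11)
  expect_identical(e$samples, e2$samples)
  # different seeds: different waveforms, same design magnitudes up to the
  # min-max gain (compare unit-normalized non-DC magnitude spectra)
  e3 <- spectrum_to_envelope(curve, duration = 4, env_rate = 1000, seed = 12)
  expect_gt(mean(abs(e$samples - e3$samples)), 1e-3)
  nmag <- function(x) {
    m <- Mod(fft(x))[-1]
    m / sqrt(sum(m^2))
  }
  expect_equal(nmag(e$samples), nmag(e3$samples), tolerance = 1e-8)
  # aliasing guard
  expect_error(spectrum_to_envelope(curve, duration = 4, env_rate = 100, seed = 1),
               "aliasing")
})

test_that("LNN flattening reduces envelope fluctuation inside the band", {
  lnn <- make_low_noise_noise(2, rate = 8000, band = c(20, 3000), n_iter = 10,
                              seed = 7)
  cv <- attr(lnn, "cv_history")
  expect_length(cv, 11)
  expect_lt(cv[11], cv[1])                     # flatter than white noise
  expect_true(all(diff(cv) < 1e-3))            # nonincreasing (to tolerance)
  expect_equal(sqrt(mean(lnn^2)), 1)           # unit RMS
  # out-of-band power below 1%
  P <- Mod(fft(as.numeric(lnn)))^2
  fr <- (seq_along(P) - 1) * 8000 / length(P)
  fr <- pmin(fr, 8000 - fr)
  expect_lt(sum(P[fr < 20 | fr > 3000]) / sum(P), 0.01)
  # determinism
  lnn2 <- make_low_noise_noise(2, rate = 8000, band = c(20, 3000), n_iter = 10,
                               seed = 7)
  expect_identical(as.numeric(lnn), as.numeric(lnn2))
  expect_error(make_low_noise_noise(1, 8000, c(20, 5000), seed = 1), "rate/2")
  expect_error(make_low_noise_noise(1, 8000, n_iter = 0, seed = 1), "at least 1")
})

test_that("synthesized stimuli have the designed duration and envelope", {
  s <- synthesize_stimulus(am_params(2, 0.35), seed = 3)
  expect_equal(length(s$waveform), 4 * 44100)
  expect_gt(s$rms, 0)
  # delivered instantaneous envelope tracks the designed modulator
  env <- Mod(amnoise:::analytic_signal(s$waveform))
  expect_gt(cor(env, s$envelope), 0.8)
})

test_that("RMS equalization is an exact scalar gain", {
  set.seed(1)
  w1 <- rnorm(1000, sd = 0.1)
  w2 <- rnorm(1000, sd = 0.4)
  out <- equalize_rms(list(w1, w2), target_rms = 0.2)
  r <- vapply(out, function(x) sqrt(mean(x^2)), numeric(1))
  expect_equal(r, c(0.2, 0.2), tolerance = 1e-12)
  expect_equal(abs(cor(out[[1]], w1)), 1)      # pure gain, shape untouched
  expect_error(equalize_rms(list(numeric(10)), 0.1), "silent")
  # a stimulus already at target is unchanged
  r1 <- sqrt(mean(w1^2))
  expect_equal(equalize_rms(list(w1), r1)[[1]], w1)
})

test_that("AM spectrum estimation finds a known modulation and rejects short input", {
  rate <- 8000
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  set.seed(42)
  carrier <- rnorm(length(t))
  modulated <- (1 + 0.8 * sin(2 * pi * 3 * t)) * carrier
  sp <- estimate_am_spectrum(modulated, rate = rate)
  expect_lt(abs(am_peak(sp, compensate = TRUE) - 3), 0.26) # within one native bin
  expect_gt(min(sp$freq), 0)                               # DC excluded
  # an unmodulated carrier has no comparably dominant low-frequency peak
  sp0 <- estimate_am_spectrum(carrier, rate = rate)
  ratio <- function(s) max(s$power * s$freq) / median(s$power * s$freq)
  expect_gt(ratio(sp), ratio(sp0))
  expect_error(estimate_am_spectrum(rnorm(100), rate = 8000), "1 s")
})

test_that("designed spectral bandwidth grows with the regularity parameter", {
  f <- seq(0.01, 30, by = 0.01)
  bw <- vapply(c(0.15, 0.35, 0.75), function(s) {
    bandwidth_3db(apply_one_over_f(lognormal_am_spectrum(am_params(2, s), f)))
  }, numeric(1))
  expect_true(all(diff(bw) > 0))
})

test_that("a stimulus pool shares one carrier and a common RMS", {
  conds <- tibble::tibble(condition = c("a", "b"), m_hz = c(1, 4), sigma = 0.35)
  pool <- do.call(synthesize_pool,
                  c(list(conds, n_per_condition = 3, seed = 5), fast_synth))
  expect_length(pool$stimuli, 6)
  expect_equal(nrow(pool$manifest), 6)
  r <- pool$manifest$rms
  expect_lt(max(abs(r - 0.05)) / 0.05, 1e-9)
  expect_s3_class(pool$carrier, "lnn_carrier")
})
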