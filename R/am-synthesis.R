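#' Modulation-spectrum curve
#'
#' A light container for a one-sided modulation spectrum: strictly increasing
#' positive modulation frequencies and the nonnegative spectral magnitude at
#' each. Used both for designed spectra (on the synthesis side) and for
#' spectra estimated back from audio (on the verification side).
#'
#' @param freq Modulation frequencies in Hz, strictly increasing, all > 0.
#' @param power Nonnegative finite magnitude per frequency.
#' @return A tibble of class `spectrum_curve` with columns `freq`, `power`.
#' @export
spectrum_curve <- function(freq, power) {
  if (length(freq) != length(power)) {
    abort("`freq` and `power` must have the same length.")
  }
  if (any(freq <= 0) || any(diff(freq) <= 0)) {
    abort("`freq` must be strictly increasing and start above 0 (no DC bin).")
  }
  if (any(!is.finite(power)) || any(power < 0)) {
    abort("`power` must be finite and nonnegative.")
  }
  out <- tibble::tibble(freq = as.numeric(freq), power = as.numeric(power))
  class(out) <- c("spectrum_curve", class(out))
  out
}

#' Shifted-lognormal AM spectrum
#'
#' Evaluate the shifted lognormal
#' \deqn{f(x) = \frac{1}{(x-b)\,\sigma\sqrt{2\pi}}
#'       \exp\!\left(-\frac{(\ln(x-b)-\mu)^2}{2\sigma^2}\right)}
#' on a modulation-frequency grid. With `b = -1.2813 m` and
#' `mu = log(m - b) + sigma^2` the mode of the continuous curve is exactly the
#' designated peak frequency `m`.
#'
#' @param params A one-row [am_params()] object.
#' @param freq Frequency grid in Hz (all > 0).
#' @return A [spectrum_curve()].
#' @examples
#' lognormal_am_spectrum(am_params(2, 0.35), freq = seq(0.1, 16, by = 0.1))
#' @export
lognormal_am_spectrum <- function(params, freq) {
  params <- as_one_param(params)
  if (any(freq <= 0)) abort("`freq` must be positive (grid excludes DC).")
  # shifted lognormal == lognormal density in (x - b)
  power <- stats::dlnorm(freq - params$b, meanlog = params$mu, sdlog = params$sigma)
  spectrum_curve(freq, power)
}

as_one_param <- function(params) {
  if (!inherits(params, "am_params")) {
    abort("`params` must be created with am_params().")
  }
  if (nrow(params) != 1L) abort("`params` must contain exactly one parameter set.")
  params
}

#' Apply or undo the 1/f weighting of a modulation spectrum
#'
#' Natural envelope spectra carry a low-frequency tilt; analysis pipelines
#' remove it by multiplying by the modulation frequency. Synthesis reverses
#' that step: `apply_one_over_f()` divides each magnitude by its frequency, so
#' the designated peak `m` is the peak of the 1/f-compensated spectrum
#' (`power * freq`), not of the raw curve. `compensate_one_over_f()` is the
#' inverse, used when checking delivered stimuli.
#'
#' @param curve A [spectrum_curve()].
#' @return A [spectrum_curve()] with reweighted power.
#' @export
apply_one_over_f <- function(curve) {
  stopifnot(inherits(curve, "spectrum_curve"))
  spectrum_curve(curve$freq, curve$power / curve$freq)
}

#' @rdname apply_one_over_f
#' @export
compensate_one_over_f <- function(curve) {
  stopifnot(inherits(curve, "spectrum_curve"))
  spectrum_curve(curve$freq, curve$power * curve$freq)
}

#' Peak frequency of a modulation spectrum
#'
#' @param curve A [spectrum_curve()].
#' @param compensate Multiply by frequency (undo the 1/f tilt) before taking
#'   the argmax; this is how designated peaks are validated.
#' @return The frequency (Hz) at which the (optionally compensated) spectrum
#'   is maximal.
#' @export
am_peak <- function(curve, compensate = TRUE) {
  stopifnot(inherits(curve, "spectrum_curve"))
  p <- if (compensate) curve$power * curve$freq else curve$power
  curve$freq[which.max(p)]
}

#' 3-dB bandwidth of a modulation spectrum
#'
#' Width of the frequency region whose (optionally 1/f-compensated) power
#' stays within 3 dB of the peak, with linear interpolation at the crossings.
#' Wider bandwidth means lower temporal regularity of the corresponding
#' envelope.
#'
#' @inheritParams am_peak
#' @return Bandwidth in Hz.
#' @export
bandwidth_3db <- function(curve, compensate = TRUE) {
  stopifnot(inherits(curve, "spectrum_curve"))
  p <- if (compensate) curve$power * curve$freq else curve$power
  f <- curve$freq
  thr <- max(p) * 10^(-3 / 10)
  i_pk <- which.max(p)
  cross <- function(idx) {
    # linear interpolation between the last sub-threshold and first
    # supra-threshold grid point
    if (length(idx) == 0L) return(NA_real_)
    i <- idx[1]
    approx(p[c(i, i + 1L)], f[c(i, i + 1L)], xout = thr)$y
  }
  lo_idx <- rev(which(p[seq_len(i_pk - 1L)] < thr))
  lo <- if (length(lo_idx)) cross(lo_idx[1]) else f[1]
  hi_idx <- which(p[seq(i_pk, length(p))] < thr) + i_pk - 1L
  hi <- if (length(hi_idx)) {
    i <- hi_idx[1] - 1L
    approx(p[c(i, i + 1L)], f[c(i, i + 1L)], xout = thr)$y
  } else f[length(f)]
  hi - lo
}

# ---- FFT plumbing --------------------------------------------------------

# Analytic signal via the frequency-domain construction: double positive
# frequencies, zero negative ones. Mod() of the result is the instantaneous
# (Hilbert) envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Zero all FFT bins whose |frequency| lies outside [lo, hi]; returns the
# masked spectrum (not the signal).
fft_band_mask <- function(n, rate, lo, hi) {
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * rate / n
  abs(f) >= lo & abs(f) <= hi
}

# Exact band-limited (sinc) resampling of a real signal to n_out samples over
# the same duration, by zero-padding or truncating the spectrum.
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- fft(x)
  Y <- complex(n_out)
  k <- min(floor(n / 2), floor(n_out / 2))
  Y[1] <- X[1]
  if (k >= 1) {
    Y[2:(k + 1)] <- X[2:(k + 1)]
    Y[n_out - (1:k) + 1] <- X[n - (1:k) + 1]
  }
  # halve a Nyquist bin that lands on the new edge to keep the signal real
  if (n_out < n && n_out %% 2 == 0) {
    Y[n_out / 2 + 1] <- Re(Y[n_out / 2 + 1])
  }
  Re(fft(Y, inverse = TRUE)) / n
}

# ---- Envelope synthesis --------------------------------------------------

#' Turn a designed modulation spectrum into an amplitude envelope
#'
#' Places the curve's magnitudes on the FFT bin grid of a `duration`-second
#' signal, draws i.i.d. uniform phases on `[0, 2*pi)` (conjugate-symmetric,
#' DC bin zero), inverse-transforms, and min-max rescales the real signal to
#' `[0, 1]` so it can serve as a multiplicative amplitude envelope. The
#' rescaling preserves the designed spectrum shape up to an affine (DC +
#' gain) term. Deterministic for a fixed `seed`.
#'
#' @param curve A [spectrum_curve()]; its frequencies must be representable on
#'   the FFT bin grid (spacing `1/duration` Hz) and below `env_rate / 2`.
#' @param duration Signal duration in seconds (default 20).
#' @param env_rate Envelope sampling rate in Hz (default 1000; AM content is
#'   far below this, so synthesizing at audio rate would be wasteful).
#' @param seed Integer phase-randomization seed.
#' @return A list of class `am_envelope` with elements `samples` (in
#'   `[0, 1]`), `rate`, `seed`.
#' @export
spectrum_to_envelope <- function(curve, duration = 20, env_rate = 1000, seed) {
  stopifnot(inherits(curve, "spectrum_curve"))
  seed <- check_seed(seed)
  n <- duration * env_rate
  if (abs(n - round(n)) > 1e-9) abort("`duration * env_rate` must be an integer.")
  n <- as.integer(round(n))
  if (max(curve$freq[curve$power > 0]) > env_rate / 2) {
    abort("`env_rate` is too low to represent the curve's support (aliasing).")
  }
  bin_f <- seq_len(floor(n / 2)) / duration
  mag <- approx(curve$freq, curve$power, xout = bin_f, rule = 1)$y
  mag[is.na(mag)] <- 0
  X <- complex(n)
  n_half <- floor(n / 2)
  n_free <- if (n %% 2 == 0) n_half - 1L else n_half # bins with a free phase
  phases <- with_seed(seed, runif(n_free, 0, 2 * pi))
  X[1 + seq_len(n_free)] <- mag[seq_len(n_free)] * exp(1i * phases)
  if (n %% 2 == 0) X[n_half + 1] <- mag[n_half] # Nyquist bin: real
  X[n + 1 - seq_len(n_free)] <- Conj(X[1 + seq_len(n_free)])
  x <- Re(fft(X, inverse = TRUE)) / n
  rng <- range(x)
  samples <- (x - rng[1]) / (rng[2] - rng[1])
  structure(list(samples = samples, rate = env_rate, seed = seed),
            class = "am_envelope")
}

# ---- Low-noise noise carrier ---------------------------------------------

#' Low-noise-noise (LNN) carrier
#'
#' Broadband noise iteratively flattened so that its instantaneous envelope is
#' nearly constant: starting from band-limited white noise, each iteration
#' divides the signal by its Hilbert envelope and re-band-limits it in the
#' frequency domain. All amplitude fluctuation in a finished stimulus then
#' comes from the imposed modulator, not from the carrier.
#'
#' @param duration Duration in seconds.
#' @param rate Audio sampling rate in Hz (default 44100).
#' @param band Passband `c(lo, hi)` in Hz (default 20-20000); must satisfy
#'   `0 < lo < hi < rate / 2`.
#' @param n_iter Number of flattening iterations (default 10, >= 1).
#' @param seed Integer seed; the waveform is bit-identical across calls with
#'   the same arguments.
#' @return Unit-RMS numeric waveform of class `lnn_carrier`, with attributes
#'   `rate`, `band`, `seed`, and `cv_history` (envelope coefficient of
#'   variation before flattening and after each iteration).
#' @export
make_low_noise_noise <- function(duration, rate = 44100, band = c(20, 20000),
                                 n_iter = 10, seed) {
  seed <- check_seed(seed)
  if (n_iter < 1) abort("`n_iter` must be at least 1.")
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < rate / 2)) {
    abort("`band` must satisfy 0 < lo < hi < rate/2.")
  }
  n <- as.integer(round(duration * rate))
  x <- with_seed(seed, rnorm(n))
  mask <- fft_band_mask(n, rate, band[1], band[2])
  h <- numeric(n) # analytic-signal weights
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- fft(x)
  X[!mask] <- 0
  cv <- numeric(n_iter + 1L)
  for (i in seq_len(n_iter + 1L)) {
    a <- fft(X * h, inverse = TRUE) / n
    env <- Mod(a)
    cv[i] <- sd(env) / mean(env)
    if (i > n_iter) break
    sig <- Re(a) / pmax(env, 1e-12)
    X <- fft(sig)
    X[!mask] <- 0
  }
  out <- Re(fft(X, inverse = TRUE)) / n
  out <- out / rms(out)
  structure(out, rate = rate, band = band, seed = seed, cv_history = cv,
            class = "lnn_carrier")
}

# ---- Stimulus synthesis --------------------------------------------------

#' Synthesize one AM noise stimulus
#'
#' Runs the full design chain: shifted-lognormal spectrum on the FFT bin grid
#' (1/`duration` Hz spacing, up to `fmax`), 1/f weighting, random-phase
#' inverse FFT to a `duration`-second envelope, band-limited upsampling to the
#' audio rate (clipped to `[0, 1]` to remove interpolation overshoot),
#' multiplication with an LNN carrier, and extraction of the middle
#' `extract`-second segment.
#'
#' @param params A one-row [am_params()].
#' @param seed Integer seed; envelope phases and (if not supplied) the carrier
#'   derive independent streams from it.
#' @param rate Audio sampling rate in Hz (default 44100).
#' @param duration Pre-extraction signal duration in seconds (default 20).
#' @param extract Extracted stimulus duration in seconds (default 4).
#' @param env_rate Internal envelope synthesis rate in Hz (default 1000).
#' @param fmax Upper edge of the designed modulation band in Hz (default 64).
#' @param carrier Optional precomputed [make_low_noise_noise()] carrier of
#'   matching `rate` and `duration` (a stimulus pool shares one carrier; the
#'   carrier is envelope-flat by construction, so it contributes no AM).
#' @return A list of class `am_stimulus`: `waveform` (`extract * rate`
#'   samples), `rate`, `params`, `seed`, `rms`, and `envelope` (the designed
#'   envelope over the extracted window, at audio rate).
#' @examples
#' \donttest{
#' s <- synthesize_stimulus(am_params(2, 0.35), seed = 1)
#' length(s$waveform) / s$rate # 4 seconds
#' }
#' @export
synthesize_stimulus <- function(params, seed, rate = 44100, duration = 20,
                                extract = 4, env_rate = 1000, fmax = 64,
                                carrier = NULL) {
  params <- as_one_param(params)
  seed <- check_seed(seed)
  seeds <- stream_seeds(seed, 2)
  freq <- seq(1 / duration, fmax, by = 1 / duration)
  curve <- apply_one_over_f(lognormal_am_spectrum(params, freq))
  env <- spectrum_to_envelope(curve, duration, env_rate, seed = seeds[1])
  n_audio <- as.integer(round(duration * rate))
  env_up <- clip01(fft_resample(env$samples, n_audio))
  if (is.null(carrier)) {
    band <- c(20, min(20000, rate / 2 - 1))
    carrier <- make_low_noise_noise(duration, rate, band = band, seed = seeds[2])
  }
  if (length(carrier) != n_audio) {
    abort("`carrier` length does not match `duration * rate`.")
  }
  wave <- env_up * as.numeric(carrier)
  i0 <- as.integer(round((duration - extract) / 2 * rate))
  idx <- (i0 + 1):(i0 + as.integer(round(extract * rate)))
  structure(
    list(waveform = wave[idx], rate = rate, params = params, seed = seed,
         rms = rms(wave[idx]), envelope = env_up[idx]),
    class = "am_stimulus"
  )
}

#' @export
print.am_stimulus <- function(x, ...) {
  cat(sprintf("<am_stimulus: m = %g Hz, sigma = %g, %.1f s @ %d Hz, rms = %.4g, seed = %d>\n",
              x$params$m, x$params$sigma, length(x$waveform) / x$rate,
              x$rate, x$rms, x$seed))
  invisible(x)
}

#' Synthesize a stimulus pool for an experiment
#'
#' Generates `n_per_condition` stimuli for every row of a condition table and
#' equalizes their RMS. One LNN carrier (seeded from `seed`) is shared across
#' the pool; per-stimulus variation comes from the modulator phases.
#'
#' @param conditions A data frame with columns `m_hz` and `sigma` (e.g. a
#'   [condition_grid()]).
#' @param n_per_condition Stimuli per condition; defaults to the grid's
#'   `pool_size` attribute (100 for Experiment 1, 50 for Experiments 2-4).
#' @param seed Master seed for the pool.
#' @param target_rms RMS level all stimuli are equalized to (default 0.05
#'   full-scale, leaving headroom after modulation).
#' @param ... Passed to [synthesize_stimulus()].
#' @return A list with `stimuli` (list of `am_stimulus`) and `manifest`
#'   (tibble: `stimulus_id`, `condition`, `m_hz`, `sigma`, `seed`, `rms`).
#' @export
synthesize_pool <- function(conditions, n_per_condition = NULL, seed,
                            target_rms = 0.05, ...) {
  seed <- check_seed(seed)
  n_per_condition <- n_per_condition %||% attr(conditions, "pool_size") %||%
    abort("`n_per_condition` is required when `conditions` has no pool_size attribute.")
  dots <- list(...)
  rate <- dots$rate %||% 44100
  duration <- dots$duration %||% 20
  n_total <- nrow(conditions) * n_per_condition
  seeds <- stream_seeds(seed, n_total + 1L)
  carrier <- make_low_noise_noise(duration, rate,
                                  band = c(20, min(20000, rate / 2 - 1)),
                                  seed = seeds[n_total + 1L])
  stim <- vector("list", n_total)
  rows <- vector("list", n_total)
  k <- 0L
  for (i in seq_len(nrow(conditions))) {
    p <- am_params(conditions$m_hz[i], conditions$sigma[i])
    for (j in seq_len(n_per_condition)) {
      k <- k + 1L
      stim[[k]] <- synthesize_stimulus(p, seed = seeds[k], carrier = carrier, ...)
      rows[[k]] <- tibble::tibble(
        stimulus_id = sprintf("c%02d_s%03d", i, j),
        condition = if ("condition" %in% names(conditions)) conditions$condition[i]
                    else sprintf("c%02d", i),
        m_hz = conditions$m_hz[i], sigma = conditions$sigma[i],
        seed = seeds[k]
      )
    }
  }
  stim <- equalize_rms(stim, target_rms)
  manifest <- dplyr::bind_rows(rows)
  manifest$rms <- purrr::map_dbl(stim, "rms")
  list(stimuli = stim, manifest = manifest, carrier = carrier)
}

#' Equalize RMS across stimuli
#'
#' Rescales every waveform by a scalar gain so all stimuli share
#' `target_rms`; nothing is re-synthesized.
#'
#' @param stimuli A list of `am_stimulus` objects (or bare numeric waveforms).
#' @param target_rms Target root-mean-square value (> 0).
#' @return The input list with waveforms rescaled and `rms` fields updated.
#' @export
equalize_rms <- function(stimuli, target_rms = 0.05) {
  stopifnot(target_rms > 0)
  purrr::map(stimuli, function(s) {
    w <- if (inherits(s, "am_stimulus")) s$waveform else s
    r <- rms(w)
    if (r == 0) abort("Cannot equalize an all-zero (silent) stimulus.")
    g <- target_rms / r
    if (inherits(s, "am_stimulus")) {
      s$waveform <- s$waveform * g
      s$rms <- rms(s$waveform)
      s
    } else {
      s * g
    }
  })
}

# ---- Verification: spectrum estimation back from audio -------------------

#' Estimate the AM spectrum of a waveform
#'
#' Extracts the amplitude envelope (analytic-signal magnitude), band-limits it
#' to `fmax` and resamples to a low internal rate, removes the mean, and
#' returns the zero-padded magnitude spectrum up to `fmax`. Pair with
#' [compensate_one_over_f()] or `am_peak(compensate = TRUE)` to check the
#' designated peak of a delivered stimulus.
#'
#' @param waveform Numeric audio samples (or an `am_stimulus`), >= 1 s.
#' @param rate Audio sampling rate in Hz (taken from the stimulus if one is
#'   given).
#' @param fmax Upper analysis frequency in Hz (default 64).
#' @param env_rate Internal envelope rate in Hz (default 256).
#' @param pad Zero-padding factor for spectral interpolation (default 8; the
#'   returned grid spacing is `1 / (pad * duration)` Hz).
#' @return A [spectrum_curve()] over `(0, fmax]`; the DC bin is excluded by
#'   construction.
#' @export
estimate_am_spectrum <- function(waveform, rate = NULL, fmax = 64,
                                 env_rate = 256, pad = 8) {
  if (inherits(waveform, "am_stimulus")) {
    rate <- waveform$rate
    waveform <- waveform$waveform
  }
  if (is.null(rate)) abort("`rate` is required for a bare waveform.")
  n <- length(waveform)
  dur <- n / rate
  if (dur < 1) abort("`waveform` must be at least 1 s long.")
  env <- Mod(analytic_signal(waveform))
  n_env <- as.integer(round(dur * env_rate))
  env_ds <- fft_resample(env, n_env) # implicit low-pass at env_rate / 2
  env_ds <- env_ds - mean(env_ds)
  padded <- c(env_ds, numeric((pad - 1L) * n_env))
  mag <- Mod(fft(padded)) / n_env
  f <- seq_along(padded[-1]) / (pad * dur)
  keep <- f <= fmax
  spectrum_curve(f[keep], mag[-1][keep])
}

# Power spectrum of the envelope derivative of one waveform, at the native
# bin spacing 1/duration Hz. Differentiating the envelope applies the x1/f
# compensation *before* the excerpt-window smearing, which is the order in
# which the physics applies it; spectra from several stimuli can then be
# power-averaged without magnitude bias.
deriv_power_spectrum <- function(waveform, rate) {
  env <- Mod(analytic_signal(waveform))
  d <- diff(env) * rate
  d <- d - mean(d)
  Mod(fft(c(d, 0)))^2
}

#' Estimate the delivered peak AM frequency of a set of stimuli
#'
#' Measures the designated peak frequency carried by synthesized audio. For
#' each stimulus the instantaneous envelope is extracted, differentiated
#' (which applies the 1/f compensation ahead of the excerpt-window smearing),
#' and its power spectrum accumulated; the designed spectral family -- the
#' squared lognormal, smeared by the known Fejer kernel of the rectangular
#' excerpt window -- is then fitted to the averaged spectrum by least squares
#' on the amplitude scale, together with two nuisance terms (the carrier's own
#' envelope-derivative spectrum, if the carrier is available, and an f^2
#' noise floor). The fitted peak location is returned. A matched-model fit is
#' used because a 4-s excerpt only resolves ~0.25 Hz: a bare argmax of so
#' short a window is both biased (asymmetric leakage) and noisy.
#'
#' @param stimuli A list of `am_stimulus` objects sharing one `(m, sigma)`
#'   design (e.g. one condition of a pool).
#' @param carrier Optional LNN carrier the stimuli were modulated onto; its
#'   middle-segment envelope spectrum is included as a nuisance regressor.
#' @param sigma Design regularity parameter assumed by the fit (default
#'   0.35); the fit verifies the delivered peak given the design family.
#' @param fmax Upper fit frequency in Hz (default 16).
#' @param duration Pre-extraction design duration in seconds (default 20);
#'   sets the design line spacing `1/duration` Hz.
#' @param peak_range Search range for the peak, Hz.
#' @return The estimated peak AM frequency in Hz.
#' @export
estimate_am_peak <- function(stimuli, carrier = NULL, sigma = 0.35, fmax = 16,
                             duration = 20, peak_range = c(0.3, 10)) {
  stopifnot(length(stimuli) >= 1, inherits(stimuli[[1]], "am_stimulus"))
  rate <- stimuli[[1]]$rate
  n_out <- length(stimuli[[1]]$waveform)
  T_win <- n_out / rate
  acc <- NULL
  for (st in stimuli) {
    P <- deriv_power_spectrum(st$waveform, rate)
    acc <- if (is.null(acc)) P else acc + P
  }
  acc <- acc / length(stimuli)
  f_all <- (seq_along(acc) - 1) / T_win
  keep <- f_all > 0 & f_all <= fmax
  f <- f_all[keep]
  P <- acc[keep]
  Pc <- if (!is.null(carrier)) {
    i0 <- as.integer(round((length(carrier) / rate - T_win) / 2 * rate))
    seg <- as.numeric(carrier)[(i0 + 1):(i0 + n_out)]
    deriv_power_spectrum(seg, rate)[keep]
  }
  uk <- seq(1 / duration, 64, by = 1 / duration)
  sinc2 <- function(x) { s <- (sin(pi * x) / (pi * x))^2; s[abs(x) < 1e-9] <- 1; s }
  Kmat <- outer(f, uk, function(a, b) sinc2((a - b) * T_win))
  obj <- function(lm_) {
    LN <- lognormal_am_spectrum(am_params(exp(lm_), sigma), uk)$power
    base <- as.vector(Kmat %*% (LN^2)) * (2 * pi)^2
    X <- cbind(base, Pc, (2 * pi * f)^2)
    cf <- pmax(coef(stats::lm.fit(X, P)), 0)
    sum((sqrt(P) - sqrt(as.vector(X %*% cf)))^2)
  }
  grid <- seq(log(peak_range[1]), log(peak_range[2]), length.out = 40)
  vals <- vapply(grid, obj, numeric(1))
  g0 <- grid[which.min(vals)]
  opt <- stats::optimize(obj, interval = c(g0 - 0.25, g0 + 0.25), tol = 1e-4)
  exp(opt$minimum)
}

#' Verify the delivered peaks of a stimulus pool
#'
#' Applies [estimate_am_peak()] per condition of a [synthesize_pool()] result.
#'
#' @param pool A list as returned by [synthesize_pool()].
#' @param ... Passed to [estimate_am_peak()] (each condition's design `sigma`
#'   is supplied automatically).
#' @return A tibble with one row per condition: `condition`, `m_hz`, `sigma`,
#'   `m_est`, `rel_error`.
#' @export
estimate_pool_peaks <- function(pool, ...) {
  man <- pool$manifest
  conds <- dplyr::distinct(man, .data$condition, .data$m_hz, .data$sigma)
  purrr::pmap_dfr(conds, function(condition, m_hz, sigma) {
    idx <- which(man$condition == condition & man$m_hz == m_hz & man$sigma == sigma)
    m_est <- estimate_am_peak(pool$stimuli[idx], carrier = pool$carrier,
                              sigma = sigma, ...)
    tibble::tibble(condition = condition, m_hz = m_hz, sigma = sigma,
                   m_est = m_est, rel_error = m_est / m_hz - 1)
  })
}
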