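#' Headphone-screening stimuli and scoring
#'
#' Online listeners are screened with a 3-alternative forced choice: among
#' three 1-s, 200-Hz pure tones -- a binaurally in-phase loud tone, an
#' antiphase loud tone, and an in-phase quiet tone 6 dB below the loud one --
#' pick the quietest. Over loudspeakers the antiphase tone cancels in the air
#' and becomes the quietest, so only headphone listeners can reliably pick
#' the quiet in-phase tone.
#'
#' `make_screening_trial()` builds one trial's stereo tones with raised-cosine
#' (Hann half-window) 100-ms onset/offset ramps. The loud reference amplitude
#' is 0.5 full-scale and the quiet gain is exactly `10^(-6/20)`, so the level
#' difference is exactly -6.0 dB.
#'
#' @param seed Integer seed (selects the presentation order).
#' @param rate Audio sampling rate in Hz (> 400).
#' @param order Optional explicit permutation of `1:3` overriding the random
#'   order.
#' @return A list of class `screening_triplet`: `tones` (named list of
#'   two-column L/R matrices for `inphase_loud`, `antiphase_loud`,
#'   `inphase_quiet`), `order` (presentation order of those labels),
#'   `correct` (presented position of the quiet in-phase tone), `rate`.
#' @export
make_screening_trial <- function(seed, rate = 44100, order = NULL) {
  seed <- check_seed(seed)
  if (rate <= 400) abort("`rate` must exceed 400 Hz for a 200-Hz tone.")
  n <- as.integer(round(rate))
  t <- (seq_len(n) - 1) / rate
  tone <- 0.5 * sin(2 * pi * 200 * t)
  n_ramp <- as.integer(round(0.1 * rate))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 0.5) / n_ramp))
  tone[seq_len(n_ramp)] <- tone[seq_len(n_ramp)] * ramp
  tone[n - n_ramp + seq_len(n_ramp)] <- tone[n - n_ramp + seq_len(n_ramp)] * rev(ramp)
  quiet_gain <- 10^(-6 / 20)
  tones <- list(
    inphase_loud   = cbind(left = tone, right = tone),
    antiphase_loud = cbind(left = tone, right = -tone),
    inphase_quiet  = cbind(left = tone * quiet_gain, right = tone * quiet_gain)
  )
  order <- order %||% with_seed(seed, sample(3L))
  structure(
    list(tones = tones, order = names(tones)[order],
         correct = which(names(tones)[order] == "inphase_quiet"), rate = rate),
    class = "screening_triplet"
  )
}

#' Build a full screening block of 6 trials
#'
#' The three tones are counterbalanced over the 6 trials: each of the 6
#' permutations of the three positions occurs exactly once, in a
#' seed-determined order.
#'
#' @inheritParams make_screening_trial
#' @return A list of 6 `screening_triplet`s.
#' @export
make_screening_block <- function(seed, rate = 44100) {
  seed <- check_seed(seed)
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  shuffle <- with_seed(seed, sample(6L))
  lapply(seq_len(6L), function(i) {
    make_screening_trial(seed = seed + i, rate = rate, order = perms[[shuffle[i]]])
  })
}

#' Simulate playback physics of a screening trial
#'
#' Under `headphones`, each ear receives its channel unchanged; under
#' `loudspeaker`, the two channels sum in the air (ideal mono mixdown
#' `(left + right) / 2`), which cancels the antiphase tone exactly.
#'
#' @param triplet A [make_screening_trial()] result.
#' @param mode `"headphones"` or `"loudspeaker"`.
#' @return A tibble with one row per tone in presentation order: `position`,
#'   `tone`, `rms` (perceived level under the playback mode).
#' @export
render_playback <- function(triplet, mode = c("headphones", "loudspeaker")) {
  stopifnot(inherits(triplet, "screening_triplet"))
  mode <- rlang::arg_match(mode)
  purrr::imap_dfr(triplet$order, function(label, pos) {
    ch <- triplet$tones[[label]]
    level <- if (mode == "headphones") {
      # binaural presentation: overall level across the two ears
      rms(as.numeric(ch))
    } else {
      rms((ch[, 1] + ch[, 2]) / 2)
    }
    tibble::tibble(position = pos, tone = label, rms = level)
  })
}

#' Score a headphone-screening block
#'
#' @param responses Integer vector of 6 picked positions (1-3).
#' @param answers Integer vector of 6 correct positions, or a list of 6
#'   `screening_triplet`s.
#' @return A list: `n_correct`, `passed` (TRUE iff at least 5 of 6 correct).
#' @export
score_screening <- function(responses, answers) {
  if (is.list(answers)) answers <- purrr::map_int(answers, "correct")
  if (length(responses) != 6L || length(answers) != 6L) {
    abort("Screening is scored over exactly 6 trials.")
  }
  n_correct <- sum(responses == answers)
  list(n_correct = n_correct, passed = n_correct >= 5L)
}
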