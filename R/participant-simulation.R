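#' Specify a simulated participant population
#'
#' Defines the generative population for synthetic experiments. Each
#' participant carries a true response slope `beta` (probability of the
#' "speech"/target response per unit of the manipulated AM parameter), an
#' intercept `alpha` (response probability at the reference level), a lapse
#' rate `lambda` (probability of answering at random), a General Musical
#' Sophistication score on 18-126, and compliance flags used to exercise the
#' exclusion filters. `(beta, msi)` are bivariate normal with correlation
#' `rho`; `msi` is truncated to `[18, 126]` by resampling so no boundary
#' atoms appear.
#'
#' The defaults mirror the first judgment experiment: a positive mean slope
#' whose mean/SD ratio equals the observed standardized effect (Cohen's d =
#' 0.68), the published sophistication norm (mean 81.58, SD 20.62), and a
#' slope-sophistication correlation of 0.2.
#'
#' @param n Number of participants.
#' @param beta_mean,beta_sd Mean and SD of the true slope (per Hz or per
#'   sigma unit).
#' @param alpha_mean,alpha_sd Mean and SD of the intercept probability.
#' @param msi_mean,msi_sd Sophistication norm parameters (defaults 81.58,
#'   20.62).
#' @param rho Pearson correlation between slope and sophistication.
#' @param lapse_max Lapse rates are uniform on `[0, lapse_max]` (< 0.5).
#' @param frac_all_same,frac_probe_fail,frac_biased Fractions of
#'   non-compliant archetypes: constant responders, probe-failers (probe
#'   accuracy ~50%), and biased responders (response rate forced to
#'   `bias_target`).
#' @param bias_target Response-1 rate emitted by biased responders.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n = 129, beta_mean = 0.08,
                            beta_sd = beta_mean / 0.68,
                            alpha_mean = 0.5, alpha_sd = 0.12,
                            msi_mean = 81.58, msi_sd = 20.62, rho = 0.2,
                            lapse_max = 0.1, frac_all_same = 0,
                            frac_probe_fail = 0, frac_biased = 0,
                            bias_target = 0.8) {
  if (abs(rho) > 1) abort("`rho` must be in [-1, 1].")
  if (msi_sd < 0 || beta_sd < 0) abort("SDs must be nonnegative.")
  if (lapse_max < 0 || lapse_max >= 0.5) abort("`lapse_max` must be in [0, 0.5).")
  if (frac_all_same + frac_probe_fail + frac_biased > 1) {
    abort("Archetype fractions must sum to at most 1.")
  }
  structure(as.list(environment()), class = "population_spec")
}

#' Sample participant profiles from a population
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per participant: `participant_id`, `beta`,
#'   `alpha`, `lapse`, `msi`, `archetype` (`"compliant"`, `"all_same"`,
#'   `"probe_fail"` or `"biased"`), `probe_failure_rate`, `bias_target`, and
#'   the completion/screening flags (`completed`, `questionnaire`,
#'   `headphone_pass`) the exclusion filters read, all TRUE by default.
#' @export
sample_population <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  seed <- check_seed(seed)
  n <- spec$n
  with_seed(seed, {
    Sigma <- matrix(c(spec$beta_sd^2,
                      spec$rho * spec$beta_sd * spec$msi_sd,
                      spec$rho * spec$beta_sd * spec$msi_sd,
                      spec$msi_sd^2), 2)
    if (spec$beta_sd == 0 || spec$msi_sd == 0) {
      bm <- cbind(rnorm(n, spec$beta_mean, spec$beta_sd),
                  rnorm(n, spec$msi_mean, spec$msi_sd))
    } else {
      draw <- function(k) {
        matrix(MASS::mvrnorm(k, c(spec$beta_mean, spec$msi_mean), Sigma),
               ncol = 2)
      }
      bm <- draw(n)
      # truncate msi to [18, 126] by resampling
      bad <- which(bm[, 2] < 18 | bm[, 2] > 126)
      while (length(bad)) {
        bm[bad, ] <- draw(length(bad))
        bad <- bad[bm[bad, 2] < 18 | bm[bad, 2] > 126]
      }
    }
    n_arch <- c(all_same = floor(spec$frac_all_same * n),
                probe_fail = floor(spec$frac_probe_fail * n),
                biased = floor(spec$frac_biased * n))
    archetype <- rep("compliant", n)
    slots <- sample(n, sum(n_arch))
    archetype[slots] <- rep(names(n_arch), n_arch)
    tibble::tibble(
      participant_id = sprintf("p%03d", seq_len(n)),
      beta = bm[, 1],
      alpha = pmin(0.95, pmax(0.05, rnorm(n, spec$alpha_mean, spec$alpha_sd))),
      lapse = runif(n, 0, spec$lapse_max),
      msi = bm[, 2],
      archetype = archetype,
      probe_failure_rate = ifelse(archetype == "probe_fail", 0.5, 0),
      bias_target = ifelse(archetype == "biased", spec$bias_target, NA_real_),
      completed = TRUE, questionnaire = TRUE, headphone_pass = TRUE
    )
  })
}

#' Response probability of a participant at a stimulus level
#'
#' The generative psychometric model is linear in the manipulated parameter,
#' clipped to `[0, 1]`, with a lapse mixture:
#' `p = lambda/2 + (1 - lambda) * clip(alpha + beta * (x - x_ref), 0, 1)`.
#'
#' @param profile A one-row slice of [sample_population()] output (or any
#'   list with `alpha`, `beta`, `lapse`).
#' @param x Manipulated parameter value(s) (Hz or sigma units).
#' @param x_ref Reference level at which the probability equals `alpha`
#'   (before lapses).
#' @return Response probabilities, same length as `x`.
#' @export
response_probability <- function(profile, x, x_ref = 0) {
  p <- clip01(profile$alpha + profile$beta * (x - x_ref))
  profile$lapse / 2 + (1 - profile$lapse) * p
}

#' Simulate one participant's responses to a schedule
#'
#' Testing trials draw Bernoulli responses from [response_probability()] at
#' the trial's manipulated-parameter value; probe trials are answered
#' correctly with probability `1 - probe_failure_rate`. Constant responders
#' (`archetype == "all_same"`) emit all-1 responses; biased responders emit 1
#' with their `bias_target` rate regardless of the stimulus. Deterministic
#' given `seed`.
#'
#' @param profile One participant row from [sample_population()].
#' @param schedule A [build_schedule()] tibble.
#' @param seed Integer seed.
#' @param x_ref Reference level passed to [response_probability()]; defaults
#'   to the mean of the schedule's testing levels.
#' @return The schedule tibble with columns `x_value`, `response` (0/1 on
#'   testing/practice trials) and `probe_correct` (logical, probes only)
#'   appended.
#' @export
simulate_responses <- function(profile, schedule, seed, x_ref = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"))
  seed <- check_seed(seed)
  x_var <- attr(schedule, "x_var")
  out <- tibble::as_tibble(schedule)
  out$x_value <- out[[x_var]]
  x_ref <- x_ref %||% mean(out$x_value[out$kind == "testing"])
  with_seed(seed, {
    n <- nrow(out)
    out$response <- NA_integer_
    out$probe_correct <- NA
    stim <- out$kind %in% c("testing", "practice")
    if (profile$archetype == "all_same") {
      out$response[stim] <- 1L
    } else if (profile$archetype == "biased") {
      out$response[stim] <- rbinom(sum(stim), 1L, profile$bias_target)
    } else {
      p <- response_probability(profile, out$x_value[stim], x_ref)
      out$response[stim] <- rbinom(sum(stim), 1L, p)
    }
    probes <- out$kind == "probe"
    out$probe_correct[probes] <- runif(sum(probes)) >= profile$probe_failure_rate
  })
  out
}

#' Simulate a complete experiment
#'
#' Samples a population, builds per-participant schedules, and simulates all
#' responses, yielding the two tables the analysis pipeline consumes.
#'
#' @param experiment Integer 1-4.
#' @param spec A [population_spec()].
#' @param seed Master seed; participant schedules and responses derive
#'   independent streams from it.
#' @param grid Optional [condition_grid()] override.
#' @return A list: `responses` (row-bound [simulate_responses()] tables),
#'   `participants` (profiles with covariates and flags), `grid`.
#' @export
simulate_experiment <- function(experiment, spec = population_spec(),
                                seed, grid = NULL) {
  seed <- check_seed(seed)
  grid <- grid %||% condition_grid(experiment)
  participants <- sample_population(spec, seed)
  seeds <- stream_seeds(seed + 1L, 2L * spec$n)
  responses <- purrr::map_dfr(seq_len(spec$n), function(i) {
    sched <- build_schedule(grid, seed = seeds[2 * i - 1L],
                            participant_id = participants$participant_id[i])
    simulate_responses(participants[i, ], sched, seed = seeds[2 * i])
  })
  list(responses = responses, participants = participants, grid = grid)
}
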