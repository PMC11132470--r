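#' Condition grids of the four experiments
#'
#' Returns the stimulus conditions of each experiment:
#'
#' * Experiment 1 -- peak AM frequency manipulated: 10 levels log-spaced on
#'   0.6-6.0 Hz, `sigma` fixed at 0.35; pool of 100 stimuli per condition,
#'   15 drawn per participant (150 unique stimuli).
#' * Experiment 2 -- temporal regularity manipulated at 3 peak frequencies
#'   (1, 2.5, 4 Hz) x 5 `sigma` levels log-spaced on 0.10-1.00; pool 50,
#'   10 drawn per condition (150 unique).
#' * Experiment 3 -- peak frequency manipulated: 5 levels log-spaced on
#'   0.6-6.0 Hz, `sigma` = 0.35; pool 50, 15 drawn (75 unique).
#' * Experiment 4 -- regularity manipulated: `m` fixed at 2 Hz, 5 `sigma`
#'   levels log-spaced on 0.10-1.00; pool 50, 15 drawn (75 unique).
#'
#' Only the level extremes (0.6 and 6.0 Hz) and Experiment 2's three peak
#' frequencies are fixed by the designs; the interior levels are log-spaced
#' defaults and can be overridden.
#'
#' @param experiment Integer 1-4.
#' @param m_levels,sigma_levels Optional overrides of the default levels.
#' @param pool_size,draws Optional overrides of the per-condition pool size
#'   and the per-participant draws per condition.
#' @return A tibble of class `condition_grid` with columns `condition`,
#'   `m_hz`, `sigma`, and attributes `experiment`, `pool_size`, `draws`,
#'   `x_var` (the manipulated parameter: `"m_hz"` or `"sigma"`), and
#'   `two_tasks` (TRUE for the detection experiments 3-4).
#' @examples
#' condition_grid(1)
#' @export
condition_grid <- function(experiment, m_levels = NULL, sigma_levels = NULL,
                           pool_size = NULL, draws = NULL) {
  if (!experiment %in% 1:4) abort("`experiment` must be 1, 2, 3 or 4.")
  log_space <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))
  defaults <- switch(experiment,
    list(m = log_space(0.6, 6, 10), s = 0.35, pool = 100L, draws = 15L,
         x_var = "m_hz", two_tasks = FALSE),
    list(m = c(1, 2.5, 4), s = log_space(0.10, 1.00, 5), pool = 50L,
         draws = 10L, x_var = "sigma", two_tasks = FALSE),
    list(m = log_space(0.6, 6, 5), s = 0.35, pool = 50L, draws = 15L,
         x_var = "m_hz", two_tasks = TRUE),
    list(m = 2, s = log_space(0.10, 1.00, 5), pool = 50L, draws = 15L,
         x_var = "sigma", two_tasks = TRUE)
  )
  m_levels <- m_levels %||% defaults$m
  sigma_levels <- sigma_levels %||% defaults$s
  pool_size <- pool_size %||% defaults$pool
  draws <- draws %||% defaults$draws
  grid <- tidyr::expand_grid(m_hz = m_levels, sigma = sigma_levels)
  n_unique_target <- if (experiment <= 2) 150L else 75L
  if (nrow(grid) * draws != n_unique_target) {
    abort(sprintf(
      "conditions (%d) x draws (%d) must equal %d unique stimuli for experiment %d.",
      nrow(grid), draws, n_unique_target, experiment))
  }
  if (pool_size < draws) abort("`pool_size` must be at least `draws`.")
  grid$condition <- sprintf("c%02d", seq_len(nrow(grid)))
  grid <- grid[, c("condition", "m_hz", "sigma")]
  structure(grid, experiment = as.integer(experiment),
            pool_size = as.integer(pool_size), draws = as.integer(draws),
            x_var = defaults$x_var, two_tasks = defaults$two_tasks,
            class = c("condition_grid", class(grid)))
}

#' Specify one probe (attention-check) trial
#'
#' A probe presents 1-4 brief tones without warning inside a 2-s window, with
#' random stimulus-onset asynchronies and no overlap; the listener reports the
#' count.
#'
#' @param seed Integer seed.
#' @param tone_dur Tone duration in seconds (default 0.1).
#' @return A list: `n_tones` (1-4, the correct answer), `onsets` (seconds,
#'   within `[0, 2 - tone_dur]`, non-overlapping), `tone_dur`.
#' @export
make_probe_trial <- function(seed, tone_dur = 0.1) {
  seed <- check_seed(seed)
  with_seed(seed, {
    n_tones <- sample(4L, 1L)
    repeat {
      onsets <- sort(runif(n_tones, 0, 2 - tone_dur))
      if (n_tones == 1L || all(diff(onsets) >= tone_dur)) break
    }
    list(n_tones = n_tones, onsets = onsets, tone_dur = tone_dur)
  })
}

# Draw `draws` stimulus ids per condition from the pool (without
# replacement). `pool` maps condition -> pool of ids; returns a tibble of
# the drawn stimuli with their condition parameters.
draw_stimuli <- function(grid, draws, pool_size) {
  purrr::pmap_dfr(grid, function(condition, m_hz, sigma) {
    ids <- sprintf("%s_s%03d", condition, sample(pool_size, draws))
    tibble::tibble(stimulus_id = ids, condition = condition,
                   m_hz = m_hz, sigma = sigma)
  })
}

#' Build one participant's trial schedule
#'
#' Draws the participant's unique stimuli from the pool and lays out the full
#' session. Experiments 1-2: every drawn stimulus is presented once in each
#' half of the session, independently shuffled within each half (300 testing
#' trials). Experiments 3-4: each session half holds one music and one speech
#' block in random order; all four blocks reuse the same 75 drawn stimuli,
#' shuffled within each block (150 testing trials per task). Twelve probe
#' trials are stratified roughly evenly (one inside each consecutive run of
#' 25 testing trials), a self-paced break follows every 10 testing trials,
#' and 4 practice trials (geometric midpoints of adjacent testing levels,
#' hence within but not equal to the tested values) open the session --
#' repeated before the first block of the second task in Experiments 3-4.
#'
#' @param grid A [condition_grid()].
#' @param seed Integer seed; all draws and orderings are reproducible from it.
#' @param participant_id Identifier recorded in the schedule.
#' @param pool_manifest Optional pool manifest (tibble with `stimulus_id`,
#'   `condition` columns from [synthesize_pool()]); when supplied, stimuli are
#'   drawn from it instead of from virtual ids.
#' @return A tibble of class `trial_schedule`: `participant_id`,
#'   `trial_index`, `kind` (`practice`/`testing`/`probe`), `task`
#'   (`judgment`, or `music`/`speech`), `block`, `half`, `stimulus_id`,
#'   `condition`, `m_hz`, `sigma`, `correct_probe_answer`, `break_after`.
#' @export
build_schedule <- function(grid, seed, participant_id = "p001",
                           pool_manifest = NULL) {
  stopifnot(inherits(grid, "condition_grid"))
  seed <- check_seed(seed)
  draws <- attr(grid, "draws")
  pool_size <- attr(grid, "pool_size")
  two_tasks <- attr(grid, "two_tasks")
  if (!is.null(pool_manifest)) {
    counts <- table(pool_manifest$condition)
    if (any(counts[grid$condition] < draws) || anyNA(counts[grid$condition])) {
      abort("`pool_manifest` has fewer stimuli than `draws` for some condition.")
    }
  }
  seeds <- stream_seeds(seed, 4L)
  drawn <- with_seed(seeds[1], {
    if (is.null(pool_manifest)) {
      draw_stimuli(grid, draws, pool_size)
    } else {
      pool_manifest |>
        dplyr::filter(.data$condition %in% grid$condition) |>
        dplyr::group_by(.data$condition) |>
        dplyr::slice_sample(n = draws) |>
        dplyr::ungroup() |>
        dplyr::select("stimulus_id", "condition", "m_hz", "sigma")
    }
  })

  testing <- with_seed(seeds[2], {
    if (!two_tasks) {
      dplyr::bind_rows(
        dplyr::mutate(drawn[sample(nrow(drawn)), ], half = 1L, block = 1L,
                      task = "judgment"),
        dplyr::mutate(drawn[sample(nrow(drawn)), ], half = 2L, block = 2L,
                      task = "judgment")
      )
    } else {
      purrr::map_dfr(1:2, function(h) {
        tasks <- sample(c("music", "speech"))
        purrr::imap_dfr(tasks, function(tk, i) {
          dplyr::mutate(drawn[sample(nrow(drawn)), ], half = h,
                        block = (h - 1L) * 2L + i, task = tk)
        })
      })
    }
  })
  n_testing <- nrow(testing)
  testing$kind <- "testing"

  # probes: one at a uniform position inside each consecutive run of 25
  # testing trials ("roughly even spaces")
  n_probes <- 12L
  stride <- n_testing / n_probes
  probe_after <- with_seed(seeds[3], {
    vapply(seq_len(n_probes), function(i) {
      lo <- as.integer(round((i - 1) * stride))
      # keep each probe in the middle half of its stratum so consecutive
      # gaps never exceed twice the mean gap
      span <- as.integer(round(stride))
      sample(seq(lo + ceiling(span * 0.3), lo + floor(span * 0.7)), 1L)
    }, integer(1))
  })
  probe_specs <- purrr::map(seq_len(n_probes),
                            function(i) make_probe_trial(seeds[4] + i))

  practice <- practice_trials(grid, two_tasks)

  rows <- list()
  push <- function(x) rows[[length(rows) + 1L]] <<- x
  blank <- tibble::tibble(stimulus_id = NA_character_, condition = NA_character_,
                          m_hz = NA_real_, sigma = NA_real_)
  for (i in seq_len(n_testing)) {
    tr <- testing[i, ]
    if (i == 1L || (two_tasks && tr$task != testing$task[i - 1L] &&
                    tr$half == 1L && i > 1L && testing$half[i - 1L] == 1L)) {
      # practice phase before the first block of each task (Exp 3-4) or at
      # session start (Exp 1-2)
      pk <- dplyr::mutate(practice, kind = "practice", task = tr$task,
                          block = tr$block, half = tr$half,
                          correct_probe_answer = NA_integer_)
      push(pk)
    }
    push(dplyr::mutate(tr, correct_probe_answer = NA_integer_))
    p_i <- which(probe_after == i)
    if (length(p_i) == 1L) {
      push(dplyr::mutate(blank, kind = "probe", task = tr$task,
                         block = tr$block, half = tr$half,
                         correct_probe_answer = probe_specs[[p_i]]$n_tones))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$participant_id <- participant_id
  out$trial_index <- seq_len(nrow(out))
  # self-paced break after every 10 testing trials
  test_count <- cumsum(out$kind == "testing")
  out$break_after <- out$kind == "testing" & test_count %% 10L == 0L
  out <- out[, c("participant_id", "trial_index", "kind", "task", "block",
                 "half", "stimulus_id", "condition", "m_hz", "sigma",
                 "correct_probe_answer", "break_after")]
  structure(out, experiment = attr(grid, "experiment"),
            x_var = attr(grid, "x_var"), probe_specs = probe_specs,
            seed = seed, class = c("trial_schedule", class(out)))
}

# 4 practice trials at geometric midpoints between adjacent testing levels:
# inside the tested range, never equal to a tested value.
practice_trials <- function(grid, two_tasks) {
  x_var <- attr(grid, "x_var")
  levels <- sort(unique(grid[[x_var]]))
  mids <- sqrt(levels[-1] * levels[-length(levels)])
  if (length(mids) >= 4L) {
    mids <- mids[round(seq(1, length(mids), length.out = 4L))]
  } else {
    mids <- rep_len(mids, 4L)
  }
  out <- tibble::tibble(stimulus_id = sprintf("practice_%d", seq_len(4L)))
  if (x_var == "m_hz") {
    out$m_hz <- mids
    out$sigma <- grid$sigma[1]
  } else {
    out$m_hz <- grid$m_hz[1]
    out$sigma <- mids
  }
  out$condition <- "practice"
  out
}
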