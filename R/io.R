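#' Run the full pipeline for one experiment
#'
#' Synthesize (optionally) the stimulus pool, build per-participant schedules,
#' simulate responses, analyze them, and write all artifacts under `outdir`:
#' stimulus WAVs and `stimuli.csv`, `schedules.csv`, `responses.csv`,
#' `participants.csv`, `report.json`, and a `manifest.json` sidecar carrying
#' the master seed and package version. Byte-identical outputs for a fixed
#' configuration and seed.
#'
#' @param experiment Integer 1-4.
#' @param seed Master seed.
#' @param outdir Output directory (created if missing).
#' @param n_participants Number of simulated participants (> 0).
#' @param spec A [population_spec()] (its `n` is overridden by
#'   `n_participants`).
#' @param grid Optional [condition_grid()] override.
#' @param write_audio Synthesize and write the stimulus pool as WAV files
#'   (default TRUE; the pool is the dominant cost of a run).
#' @param n_per_condition Pool size per condition when `write_audio = TRUE`
#'   (defaults to the experiment's pool size).
#' @param quiet Suppress progress messages.
#' @return The `stats_report`, invisibly; all artifacts are on disk.
#' @export
run_pipeline <- function(experiment, seed, outdir, n_participants = 24,
                         spec = population_spec(), grid = NULL,
                         write_audio = FALSE, n_per_condition = NULL,
                         quiet = FALSE) {
  seed <- check_seed(seed)
  if (n_participants < 1) abort("`n_participants` must be positive.")
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- grid %||% condition_grid(experiment)
  spec$n <- as.integer(n_participants)
  seeds <- stream_seeds(seed, 3L)

  if (write_audio) {
    say("[synthesize] experiment %d stimulus pool", experiment)
    pool <- synthesize_pool(grid, n_per_condition = n_per_condition,
                            seed = seeds[1])
    audio_dir <- file.path(outdir, "stimuli")
    dir.create(audio_dir, showWarnings = FALSE)
    man <- pool$manifest
    man$file <- file.path("stimuli", paste0(man$stimulus_id, ".wav"))
    purrr::walk2(pool$stimuli, man$file, function(s, f) {
      write_wav(s, file.path(outdir, f))
    })
    man$experiment <- experiment
    readr::write_csv(man, file.path(outdir, "stimuli.csv"))
  }

  say("[schedule+simulate] %d participants", n_participants)
  sim <- simulate_experiment(experiment, spec, seed = seeds[2], grid = grid)
  readr::write_csv(sim$responses, file.path(outdir, "responses.csv"))
  readr::write_csv(sim$participants, file.path(outdir, "participants.csv"))
  sched_cols <- setdiff(names(sim$responses), c("response", "probe_correct"))
  readr::write_csv(sim$responses[, sched_cols], file.path(outdir, "schedules.csv"))

  say("[analyze] experiment %d", experiment)
  report <- analyze_experiment(sim$responses, sim$participants, experiment)
  jsonlite::write_json(report_to_list(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(seed = seed, package = "amnoise",
         version = as.character(utils::packageVersion("amnoise")),
         experiment = experiment, n_participants = n_participants),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

# Flatten a stats_report into plain lists for JSON serialization.
report_to_list <- function(report) {
  strip <- function(x) if (is.list(x)) lapply(x, strip) else x
  list(
    experiment = report$experiment,
    n_included = report$n_included,
    exclusions = as.list(setNames(report$exclusions$n_excluded,
                                  report$exclusions$criterion)),
    mean_r2 = as.list(report$mean_r2),
    r2_difference = report$r2_difference,
    groups = lapply(report$groups, function(g) {
      list(n = g$n,
           slope_test = unclass(g$slope_test),
           logistic_slope_test = unclass(g$logistic_slope_test),
           msi_correlation = unclass(g$msi_correlation),
           welch_split = if (!is.null(g$welch_split)) unclass(g$welch_split))
    })
  )
}

#' Read deposited per-participant summary data
#'
#' Loads the study's deposited summary table (level-mean responses plus
#' covariates) from a local XLSX or CSV export and normalizes it to the
#' layout the analysis functions consume. The expected long layout has one
#' row per (participant, level): columns for the experiment, participant id,
#' task (where applicable), stimulus level, the mean response at that level,
#' and covariate columns (at minimum the General sophistication score). The
#' `col_map` argument renames differently-labelled source columns.
#'
#' @param path Path to a local `.xlsx` file (one sheet per experiment) or a
#'   `.csv` file in the long layout.
#' @param col_map Named character vector mapping the normalized names
#'   (`experiment`, `participant_id`, `task`, `level`, `response_mean`,
#'   `msi`) to the source column names; defaults to identity.
#' @return A tibble with the normalized columns; `task` is `"judgment"` when
#'   the source has no task column.
#' @export
read_s1_data <- function(path, col_map = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("Reading XLSX requires the readxl package.")
    }
    sheets <- readxl::excel_sheets(path)
    purrr::map_dfr(sheets, function(s) {
      d <- readxl::read_excel(path, sheet = s)
      if (!"experiment" %in% names(d)) d$experiment <- s
      d
    })
  } else if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    abort("`path` must be an .xlsx or .csv file.")
  }
  norm <- c(experiment = "experiment", participant_id = "participant_id",
            task = "task", level = "level", response_mean = "response_mean",
            msi = "msi")
  if (!is.null(col_map)) norm[names(col_map)] <- col_map
  required <- c("participant_id", "level", "response_mean")
  missing <- setdiff(norm[required], names(raw))
  if (length(missing)) {
    abort(sprintf("Missing column(s) in deposited data: %s",
                  paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    experiment = if (norm["experiment"] %in% names(raw)) raw[[norm["experiment"]]] else NA,
    participant_id = raw[[norm["participant_id"]]],
    task = if (norm["task"] %in% names(raw)) raw[[norm["task"]]] else "judgment",
    level = raw[[norm["level"]]],
    response_mean = raw[[norm["response_mean"]]],
    msi = if (norm["msi"] %in% names(raw)) raw[[norm["msi"]]] else NA_real_
  )
  out
}

#' Per-participant slopes from level-mean response data
#'
#' Fits the linear psychometric function to each participant's level-mean
#' responses (as deposited summary data provide), returning one slope per
#' participant (per task where present). Under a balanced design these
#' slopes equal the trial-level OLS slopes.
#'
#' @param s1 A [read_s1_data()] tibble.
#' @return A tibble: `participant_id`, `task`, `slope`, `intercept`,
#'   `r_squared`, `msi`.
#' @export
slopes_from_level_means <- function(s1) {
  s1 |>
    dplyr::group_by(.data$participant_id, .data$task) |>
    dplyr::group_modify(function(d, g) {
      dplyr::bind_cols(fit_linear(d$level, d$response_mean),
                       tibble::tibble(msi = d$msi[1]))
    }) |>
    dplyr::ungroup()
}
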