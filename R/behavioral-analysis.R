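#' Apply the data-quality exclusion criteria
#'
#' Participants are excluded, in order and by the first matching criterion,
#' if they (1) did not complete both the experiment and the questionnaire,
#' (2) failed the headphone screening (or admitted not using headphones),
#' (3) made the same response on every testing trial, (4) scored below 90%
#' on the probe trials; and, in the detection experiments (3-4) only, (5) had
#' a response-1 rate outside 50 +/- 15% in any task.
#'
#' @param responses Trial-level response table ([simulate_responses()]
#'   format: `participant_id`, `kind`, `task`, `response`, `probe_correct`).
#' @param participants Participant table with logical `completed`,
#'   `questionnaire`, `headphone_pass` columns.
#' @param experiment Integer 1-4; the bias rule applies only to 3-4.
#' @param probe_min Probe accuracy threshold (default 0.9).
#' @param bias_band Allowed response-rate band for experiments 3-4 (default
#'   `c(0.35, 0.65)`).
#' @return A list: `responses` and `participants` restricted to included
#'   participants, `ledger` (tibble `criterion`, `n_excluded`), `excluded`
#'   (per-participant first matching criterion, `NA` if retained).
#' @export
apply_exclusions <- function(responses, participants, experiment,
                             probe_min = 0.9, bias_band = c(0.35, 0.65)) {
  need <- c("participant_id", "kind", "task", "response", "probe_correct")
  if (!all(need %in% names(responses))) {
    abort(paste("`responses` must contain columns:", paste(need, collapse = ", ")))
  }
  need_p <- c("participant_id", "completed", "questionnaire", "headphone_pass")
  if (!all(need_p %in% names(participants))) {
    abort(paste("`participants` must contain columns:", paste(need_p, collapse = ", ")))
  }
  per <- responses |>
    dplyr::filter(.data$kind == "testing") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(all_same = dplyr::n_distinct(.data$response) == 1L,
                     .groups = "drop")
  probe <- responses |>
    dplyr::filter(.data$kind == "probe") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(probe_acc = mean(.data$probe_correct), .groups = "drop")
  bias <- responses |>
    dplyr::filter(.data$kind == "testing") |>
    dplyr::group_by(.data$participant_id, .data$task) |>
    dplyr::summarise(rate = mean(.data$response), .groups = "drop") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(bias_out = any(.data$rate < bias_band[1] |
                                      .data$rate > bias_band[2]),
                     .groups = "drop")
  tab <- participants |>
    dplyr::left_join(per, by = "participant_id") |>
    dplyr::left_join(probe, by = "participant_id") |>
    dplyr::left_join(bias, by = "participant_id")
  crit <- dplyr::case_when(
    !(tab$completed & tab$questionnaire) ~ "incomplete",
    !tab$headphone_pass ~ "headphone_fail",
    tab$all_same %in% TRUE ~ "all_same_responses",
    tab$probe_acc < probe_min ~ "probe_accuracy",
    experiment >= 3 & tab$bias_out %in% TRUE ~ "response_bias",
    .default = NA_character_
  )
  levels <- c("incomplete", "headphone_fail", "all_same_responses",
              "probe_accuracy", "response_bias")
  ledger <- tibble::tibble(
    criterion = levels,
    n_excluded = vapply(levels, function(l) sum(crit == l, na.rm = TRUE), 0L,
                        USE.NAMES = FALSE)
  )
  keep <- participants$participant_id[is.na(crit)]
  list(
    responses = dplyr::filter(responses, .data$participant_id %in% keep),
    participants = dplyr::filter(participants, .data$participant_id %in% keep),
    ledger = ledger,
    excluded = tibble::tibble(participant_id = participants$participant_id,
                              criterion = crit)
  )
}

#' Reconcile an exclusion ledger with the recruitment count
#'
#' @param recruited Number of recruited participants.
#' @param per_criterion_counts Nonnegative exclusion counts.
#' @return `recruited - sum(per_criterion_counts)`.
#' @export
reconcile_exclusion_counts <- function(recruited, per_criterion_counts) {
  if (any(per_criterion_counts < 0)) abort("Exclusion counts must be nonnegative.")
  n <- recruited - sum(per_criterion_counts)
  if (n < 0) abort("Exclusions exceed the recruitment count.")
  n
}

# ---- Per-participant psychometric fits -----------------------------------

#' Linear psychometric fit for one participant
#'
#' Ordinary least squares of the binary responses on the manipulated
#' parameter, at the trial level. If the responses have zero variance the
#' slope is 0 and R^2 is defined as 0 (such participants are normally removed
#' upstream by the all-same exclusion).
#'
#' @param x Manipulated parameter values, one per trial (at least 2 distinct).
#' @param y Binary responses (0/1).
#' @return A tibble row: `slope`, `intercept`, `r_squared`.
#' @export
fit_linear <- function(x, y) {
  if (length(unique(x)) < 2L) abort("`x` must contain at least 2 distinct levels.")
  if (var(y) == 0) {
    return(tibble::tibble(slope = 0, intercept = mean(y), r_squared = 0))
  }
  fit <- lm(y ~ x)
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared)
}

#' Bounded logistic psychometric fit for one participant
#'
#' Least-squares fit of `f(x; a, b) = 1 / (1 + exp(-b (x - a)))` to the
#' trial-level binary responses, with the midpoint `a` constrained to the
#' tested stimulus range. Least squares (not likelihood) keeps R^2 on the
#' same sum-of-squares basis as [fit_linear()], so the two models'
#' goodness-of-fit is directly comparable. Five multi-start initializations
#' over an `(a, slope)` grid guard against local minima.
#'
#' @param x,y Trial-level data as in [fit_linear()] (>= 3 distinct levels).
#' @param bounds Allowed range for `a` (default: range of the tested levels).
#' @return A tibble row: `a`, `slope`, `r_squared`, `converged`.
#' @export
fit_logistic <- function(x, y, bounds = range(x)) {
  if (length(unique(x)) < 3L) abort("`x` must contain at least 3 distinct levels.")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    return(tibble::tibble(a = mean(bounds), slope = 0, r_squared = 0,
                          converged = TRUE))
  }
  sse <- function(par) {
    p <- 1 / (1 + exp(-par[2] * (x - par[1])))
    sum((y - p)^2)
  }
  span <- diff(bounds)
  starts <- expand.grid(
    a = seq(bounds[1] + 0.1 * span, bounds[2] - 0.1 * span, length.out = 5),
    b = c(-10, -2, 2, 10, 30) / span
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      optim(c(starts$a[i], starts$b[i]), sse, method = "L-BFGS-B",
            lower = c(bounds[1], -Inf), upper = c(bounds[2], Inf)),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    return(tibble::tibble(a = mean(bounds), slope = 0, r_squared = 0,
                          converged = FALSE))
  }
  tibble::tibble(a = best$par[1], slope = best$par[2],
                 r_squared = 1 - best$value / ss_tot,
                 converged = best$convergence == 0)
}

#' Fit linear and logistic psychometric functions per participant
#'
#' Runs [fit_linear()] and [fit_logistic()] on every participant's testing
#' trials. In the regularity experiment with several peak frequencies
#' (Experiment 2), responses are fitted separately per peak frequency; in the
#' detection experiments (3-4), separately per task. The grouping is chosen
#' from the response table's attributes but can be overridden.
#'
#' @param responses Trial-level table with `participant_id`, `kind`,
#'   `x_value`, `response` (plus `task`, `m_hz` for grouped designs).
#' @param group_by Extra grouping column(s) beyond `participant_id`
#'   (e.g. `"m_hz"` for Experiment 2, `"task"` for Experiments 3-4); `NULL`
#'   for none.
#' @param bounds Logistic midpoint bounds; default: range of tested levels.
#' @return A tibble of class `psychometric_fits`: one row per group with
#'   `slope`, `intercept`, `r_squared` (linear) and `log_a`, `log_slope`,
#'   `log_r_squared`, `log_converged` (logistic).
#' @export
fit_psychometric <- function(responses, group_by = NULL, bounds = NULL) {
  test <- dplyr::filter(responses, .data$kind == "testing")
  bounds <- bounds %||% range(test$x_value)
  keys <- c("participant_id", group_by)
  out <- test |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, g) {
      lin <- fit_linear(d$x_value, d$response)
      logi <- fit_logistic(d$x_value, d$response, bounds = bounds)
      dplyr::bind_cols(lin, dplyr::rename_with(logi, ~ paste0("log_", .x)))
    }) |>
    dplyr::ungroup()
  class(out) <- c("psychometric_fits", class(out))
  out
}

#' Mean R-squared difference between the linear and logistic fits
#'
#' @param fits A [fit_psychometric()] table.
#' @return The paired mean of `r_squared - log_r_squared` across rows.
#' @export
compare_models <- function(fits) {
  mean(fits$r_squared - fits$log_r_squared)
}

# ---- Group-level inference -----------------------------------------------

#' One-sample t-test on response slopes
#'
#' Tests whether the mean slope differs from `mu` (two-tailed), with Cohen's
#' d = mean / SD.
#'
#' @param slopes Numeric vector of per-participant slopes.
#' @param mu Null value (default 0).
#' @return An object of class `slope_test`: `t`, `df`, `p`, `d`, `mean`,
#'   `sd`, `se`, `n`.
#' @export
one_sample_slope_test <- function(slopes, mu = 0) {
  n <- length(slopes)
  if (n < 2L) abort("Need at least 2 slopes.")
  s <- sd(slopes)
  if (s == 0) abort("Slopes have zero variance.")
  m <- mean(slopes) - mu
  t <- m / (s / sqrt(n))
  structure(
    list(t = t, df = n - 1L, p = 2 * pt(-abs(t), n - 1L), d = m / s,
         mean = mean(slopes), sd = s, se = s / sqrt(n), n = n),
    class = "slope_test"
  )
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("One-sample t-test on slopes: t(%d) = %.3f, p = %.3g, d = %.3f (n = %d)\n",
              x$df, x$t, x$p, x$d, x$n))
  invisible(x)
}

#' Pearson correlation between slopes and a covariate
#'
#' Computes the correlation with `df = n - 2` and a two-tailed p-value, both
#' on all points and after removing flagged outliers. An outlier is a point
#' whose standardized residual from the OLS line of `covariate` on `slopes`
#' exceeds `outlier_sd` in absolute value (the criterion is configurable;
#' both estimates are always reported).
#'
#' @param slopes,covariate Numeric vectors (n >= 3).
#' @param outlier_sd Standardized-residual threshold (default 3).
#' @return An object of class `slope_correlation`: `r`, `df`, `p`, and
#'   `r_no_outlier`, `df_no_outlier`, `p_no_outlier`, `n_outliers`,
#'   `outliers` (indices).
#' @export
correlate_slopes <- function(slopes, covariate, outlier_sd = 3) {
  if (length(slopes) != length(covariate)) abort("Lengths differ.")
  n <- length(slopes)
  if (n < 3L) abort("Need at least 3 pairs.")
  if (sd(slopes) == 0 || sd(covariate) == 0) abort("Zero variance input.")
  pearson <- function(a, b) {
    r <- cor(a, b)
    df <- length(a) - 2L
    t <- r * sqrt(df / (1 - r^2))
    list(r = r, df = df, p = 2 * pt(-abs(t), df))
  }
  full <- pearson(slopes, covariate)
  res <- stats::rstandard(lm(covariate ~ slopes))
  out_idx <- unname(which(abs(res) > outlier_sd))
  no_out <- if (length(out_idx)) {
    pearson(slopes[-out_idx], covariate[-out_idx])
  } else full
  structure(
    list(r = full$r, df = full$df, p = full$p,
         r_no_outlier = no_out$r, df_no_outlier = no_out$df,
         p_no_outlier = no_out$p, n_outliers = length(out_idx),
         outliers = out_idx),
    class = "slope_correlation"
  )
}

#' @export
print.slope_correlation <- function(x, ...) {
  cat(sprintf("r(%d) = %.3f, p = %.3g; without %d outlier(s): r(%d) = %.3f, p = %.3g\n",
              x$df, x$r, x$p, x$n_outliers, x$df_no_outlier, x$r_no_outlier,
              x$p_no_outlier))
  invisible(x)
}

#' Welch test between covariate values of positive- and negative-slope groups
#'
#' Splits participants at slope = 0 and compares the covariate between the
#' two groups with an unequal-variance two-sample t-test
#' (Welch-Satterthwaite fractional degrees of freedom). Cohen's d uses the
#' pooled SD.
#'
#' @param slopes Numeric vector; the groups are `slopes > 0` vs `slopes <= 0`.
#' @param covariate Numeric vector, same length.
#' @return An object of class `welch_test`: `t`, `df` (fractional), `p`,
#'   `d`, `n_pos`, `n_neg`, `mean_pos`, `mean_neg`.
#' @export
split_group_welch <- function(slopes, covariate) {
  g1 <- covariate[slopes > 0]
  g2 <- covariate[slopes <= 0]
  if (!length(g1) || !length(g2)) abort("One of the slope-sign groups is empty.")
  n1 <- length(g1); n2 <- length(g2)
  v1 <- var(g1); v2 <- var(g2)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(g1) - mean(g2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  sd_pool <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  structure(
    list(t = t, df = df, p = 2 * pt(-abs(t), df),
         d = abs(mean(g1) - mean(g2)) / sd_pool,
         n_pos = n1, n_neg = n2, mean_pos = mean(g1), mean_neg = mean(g2)),
    class = "welch_test"
  )
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t(%.2f) = %.3f, p = %.3g, d = %.3f (n = %d vs %d)\n",
              x$df, x$t, x$p, x$d, x$n_pos, x$n_neg))
  invisible(x)
}

#' Required sample size for a one-sample t-test (noncentral-t power)
#'
#' Smallest integer n such that a two-tailed one-sample t-test with effect
#' size d (noncentrality `d * sqrt(n)`, df `n - 1`) reaches the target power
#' at level `alpha`. Exact noncentral-t computation with an integer search.
#'
#' @param d Standardized effect size (> 0).
#' @param alpha Two-tailed significance level.
#' @param power Target power.
#' @param n_max Search limit.
#' @return The required n (integer).
#' @export
power_required_n <- function(d, alpha = 0.05, power = 0.8, n_max = 1e6) {
  if (d <= 0) abort("`d` must be positive.")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("`alpha` and `power` must be in (0, 1).")
  }
  for (n in 2:n_max) {
    if (power_one_sample_t(n, d, alpha) >= power) return(n)
  }
  abort("Target power not attainable within `n_max`.")
}

#' @rdname power_required_n
#' @param n Sample size.
#' @export
power_one_sample_t <- function(n, d, alpha = 0.05) {
  tc <- qt(1 - alpha / 2, n - 1)
  ncp <- d * sqrt(n)
  pt(-tc, n - 1, ncp = ncp) + 1 - pt(tc, n - 1, ncp = ncp)
}

#' Cohen's d from summary statistics
#'
#' @param mean1,mean2 Group means.
#' @param sd Common (norm) standard deviation (> 0).
#' @return `abs(mean1 - mean2) / sd`.
#' @export
cohens_d_from_summary <- function(mean1, mean2, sd) {
  if (sd <= 0) abort("`sd` must be positive.")
  abs(mean1 - mean2) / sd
}

# ---- Whole-experiment report ---------------------------------------------

#' Run the full statistical pipeline on one experiment's data
#'
#' Applies the exclusion criteria, fits linear and logistic psychometric
#' functions per participant (grouped per peak frequency in Experiment 2 and
#' per task in Experiments 3-4), and computes the group-level statistics:
#' one-sample t-tests on the slopes, slope-sophistication correlations (with
#' and without outliers), the split-at-zero Welch test, and the linear vs
#' logistic R^2 comparison.
#'
#' @param responses,participants Tables as produced by
#'   [simulate_experiment()] (or loaded from files in the same layout).
#' @param experiment Integer 1-4.
#' @return A list of class `stats_report`: `experiment`, `exclusions`
#'   (ledger), `n_included`, `fits`, `mean_r2` (mean +/- SE of linear R^2),
#'   `r2_difference`, and per-group `slope_test`, `msi_correlation`,
#'   `welch_split` entries.
#' @export
analyze_experiment <- function(responses, participants, experiment) {
  excl <- apply_exclusions(responses, participants, experiment)
  group_by <- switch(experiment, NULL, "m_hz", "task", "task")
  fits <- fit_psychometric(excl$responses, group_by = group_by)
  ppl <- dplyr::select(excl$participants, "participant_id", "msi")
  fits <- dplyr::left_join(fits, ppl, by = "participant_id")
  groups <- if (is.null(group_by)) list(all = fits) else split(fits, fits[[group_by]])
  per_group <- purrr::map(groups, function(g) {
    list(
      n = nrow(g),
      slope_test = one_sample_slope_test(g$slope),
      logistic_slope_test = one_sample_slope_test(g$log_slope),
      msi_correlation = correlate_slopes(g$slope, g$msi),
      welch_split = tryCatch(split_group_welch(g$slope, g$msi),
                             error = function(e) NULL)
    )
  })
  structure(
    list(
      experiment = experiment,
      exclusions = excl$ledger,
      n_included = nrow(excl$participants),
      fits = fits,
      mean_r2 = c(mean = mean(fits$r_squared),
                  se = sd(fits$r_squared) / sqrt(nrow(fits))),
      r2_difference = compare_models(fits),
      groups = per_group
    ),
    class = "stats_report"
  )
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("Experiment %d: %d participants included\n", x$experiment, x$n_included))
  cat(sprintf("  linear R^2 = %.3f +/- %.3f; mean R^2 difference (lin - log) = %.3f\n",
              x$mean_r2["mean"], x$mean_r2["se"], x$r2_difference))
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    cat(sprintf("  [%s] n = %d: ", nm, g$n)); print(g$slope_test)
  }
  invisible(x)
}

# ---- Fast simulation-based calibration -----------------------------------

#' Simulate many slope experiments under a fixed design
#'
#' Vectorized generator for calibration studies: for each replicate
#' experiment, participant slopes/intercepts/lapses are drawn from `spec`,
#' trial-level Bernoulli responses are generated under the package's linear
#' response model on the supplied design levels, per-participant OLS slopes
#' are computed in closed form (algebraically identical to [fit_linear()]),
#' and the one-sample slope t-test is run. Used to verify type-I error
#' calibration and slope recovery at scale.
#'
#' @param spec A [population_spec()]; `spec$n` participants per experiment.
#' @param x Design vector: the manipulated-parameter value of every testing
#'   trial (e.g. `rep(levels, each = 30)`).
#' @param n_reps Number of replicate experiments.
#' @param seed Integer seed.
#' @param alpha Test level for the rejection indicator.
#' @return A tibble with one row per replicate: `rep`, `mean_slope`, `t`,
#'   `p`, `reject`.
#' @export
simulate_slope_experiments <- function(spec, x, n_reps, seed, alpha = 0.05) {
  seed <- check_seed(seed)
  n <- spec$n
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  x_ref <- mean(x)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      beta <- rnorm(n, spec$beta_mean, spec$beta_sd)
      alpha_i <- pmin(0.95, pmax(0.05, rnorm(n, spec$alpha_mean, spec$alpha_sd)))
      lapse <- runif(n, 0, spec$lapse_max)
      p <- clip01(outer(x - x_ref, beta) +
                    matrix(alpha_i, length(x), n, byrow = TRUE))
      p <- matrix(lapse / 2, length(x), n, byrow = TRUE) +
        matrix(1 - lapse, length(x), n, byrow = TRUE) * p
      y <- matrix(rbinom(length(p), 1L, p), nrow(p), ncol(p))
      slopes <- as.numeric(crossprod(y, xc)) / sxx
      tt <- one_sample_slope_test(slopes)
      tibble::tibble(rep = r, mean_slope = mean(slopes), t = tt$t, p = tt$p,
                     reject = tt$p < alpha)
    })
  })
}
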