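#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a slope test
#'
#' @param x A [one_sample_slope_test()] result.
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `statistic`, `df`, `p.value`,
#'   `cohens_d`, `std.error`, `n`.
#' @method tidy slope_test
#' @export
tidy.slope_test <- function(x, ...) {
  tibble::tibble(estimate = x$mean, statistic = x$t, df = x$df,
                 p.value = x$p, cohens_d = x$d, std.error = x$se, n = x$n)
}

#' @rdname tidy.slope_test
#' @method glance slope_test
#' @export
glance.slope_test <- function(x, ...) tidy.slope_test(x)

#' Tidy a slope-covariate correlation
#'
#' @param x A [correlate_slopes()] result.
#' @param ... Unused.
#' @return A two-row tibble (with and without outliers): `subset`,
#'   `estimate`, `df`, `p.value`.
#' @method tidy slope_correlation
#' @export
tidy.slope_correlation <- function(x, ...) {
  tibble::tibble(
    subset = c("all", "outliers_removed"),
    estimate = c(x$r, x$r_no_outlier),
    df = c(x$df, x$df_no_outlier),
    p.value = c(x$p, x$p_no_outlier),
    n_outliers = c(0L, x$n_outliers)
  )
}

#' Tidy a Welch split-group test
#'
#' @param x A [split_group_welch()] result.
#' @param ... Unused.
#' @return A one-row tibble: `estimate` (mean difference), `statistic`, `df`,
#'   `p.value`, `cohens_d`, `n_pos`, `n_neg`.
#' @method tidy welch_test
#' @export
tidy.welch_test <- function(x, ...) {
  tibble::tibble(estimate = x$mean_pos - x$mean_neg, statistic = x$t,
                 df = x$df, p.value = x$p, cohens_d = x$d,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy or summarize a whole-experiment report
#'
#' `tidy()` returns the group-level inferential results, one row per
#' (group, statistic); `glance()` returns a one-row experiment summary.
#'
#' @param x An [analyze_experiment()] report.
#' @param ... Unused.
#' @method tidy stats_report
#' @export
tidy.stats_report <- function(x, ...) {
  purrr::imap_dfr(x$groups, function(g, nm) {
    dplyr::bind_rows(
      dplyr::mutate(tidy(g$slope_test), statistic_name = "slope_t", .before = 1),
      dplyr::mutate(
        tibble::tibble(estimate = g$msi_correlation$r,
                       df = g$msi_correlation$df,
                       p.value = g$msi_correlation$p),
        statistic_name = "msi_r", .before = 1),
      if (!is.null(g$welch_split)) {
        dplyr::mutate(tidy(g$welch_split), statistic_name = "welch_split",
                      .before = 1)
      }
    ) |>
      dplyr::mutate(group = nm, .before = 1)
  })
}

#' @rdname tidy.stats_report
#' @method glance stats_report
#' @export
glance.stats_report <- function(x, ...) {
  tibble::tibble(experiment = x$experiment, n_included = x$n_included,
                 mean_r2 = x$mean_r2[["mean"]], se_r2 = x$mean_r2[["se"]],
                 r2_difference = x$r2_difference)
}
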