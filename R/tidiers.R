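#' Tidy a test result
#'
#' @param x A `sync_test`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic_name`, `statistic`,
#'   `df`, `n`, `z`, `p_value`, `effect_r2`, `exact`.
#' @exportS3Method generics::tidy
tidy.sync_test <- function(x, ...) {
  tibble(method = x$method, statistic_name = x$statistic_name,
         statistic = x$statistic, df = x$df, n = x$n, z = x$z,
         p_value = x$p_value, effect_r2 = x$effect_r2, exact = x$exact)
}

#' @rdname tidy.sync_test
#' @exportS3Method generics::glance
glance.sync_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         effect_r2 = x$effect_r2)
}

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `rm_anova` from [rm_anova_linear()].
#' @param ... Unused.
#' @return A two-row tibble (omnibus condition effect and linear contrast).
#' @exportS3Method generics::tidy
tidy.rm_anova <- function(x, ...) {
  bind_rows(
    tidy(x$omnibus) |> mutate(term = "condition", df_error = x$omnibus$df_error),
    tidy(x$contrast) |> mutate(term = "linear_contrast",
                               df_error = x$contrast$df_error)
  ) |>
    select("term", dplyr::everything())
}

#' @rdname tidy.rm_anova
#' @exportS3Method generics::glance
glance.rm_anova <- function(x, ...) {
  tibble(f_condition = x$omnibus$statistic,
         p_condition = x$omnibus$p_value,
         f_linear = x$contrast$statistic,
         p_linear = x$contrast$p_value,
         r2_linear = x$contrast$effect_r2)
}

#' Tidy a basin analysis
#'
#' @param x A `basin_result` from [basin_analysis()].
#' @param ... Unused.
#' @return Per-condition summary joined with the Wilcoxon-vs-control
#'   comparison (control row has NA comparison fields).
#' @exportS3Method generics::tidy
tidy.basin_result <- function(x, ...) {
  left_join(x$summary, x$comparisons, by = "shift_pct")
}

#' @rdname tidy.basin_result
#' @exportS3Method generics::glance
glance.basin_result <- function(x, ...) {
  tibble(n_conditions = nrow(x$summary),
         n_flagged = sum(x$comparisons$significant),
         bonferroni_alpha = x$bonferroni_alpha)
}
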