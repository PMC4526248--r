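
# common result container ----------------------------------------------------

new_sync_test <- function(method, statistic_name, statistic, p_value,
                          df = NA_real_, n = NA_real_, z = NA_real_,
                          effect_r2 = NA_real_, exact = FALSE, extra = list()) {
  structure(
    c(list(method = method, statistic_name = statistic_name,
           statistic = statistic, p_value = p_value, df = df, n = n,
           z = z, effect_r2 = effect_r2, exact = exact), extra),
    class = "sync_test")
}

#' @export
print.sync_test <- function(x, ...) {
  cat(sprintf("<sync_test> %s: %s = %.4g", x$method, x$statistic_name,
              x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %g", x$df))
  if (!is.na(x$z)) cat(sprintf(", Z = %.3f", x$z))
  cat(sprintf(", p = %.4g%s", x$p_value, if (isTRUE(x$exact)) " (exact)" else ""))
  if (!is.na(x$effect_r2)) cat(sprintf(", r^2 = %.3f", x$effect_r2))
  cat("\n")
  invisible(x)
}

as_matrix_complete <- function(x) {
  m <- as.matrix(x)
  if (anyNA(m)) {
    abort("matrix has missing cells", class = "runsync_validation_error")
  }
  storage.mode(m) <- "double"
  m
}

# signed-rank / rank-sum helpers
rank_ties <- function(x) rank(x, ties.method = "average")

tie_counts <- function(r) {
  tab <- table(r)
  as.numeric(tab[tab > 1])
}

# -----------------------------------------------------------------------------

#' Friedman rank test for a within-subject design
#'
#' Ranks each participant's values across conditions (mean ranks on ties)
#' and computes the tie-corrected Friedman chi-square with `k - 1` degrees
#' of freedom. With no ties this reduces to the textbook
#' `12/(n k (k+1)) * sum(R_j^2) - 3 n (k+1)`.
#'
#' @param mat Numeric matrix or data frame, participants x conditions,
#'   complete.
#' @param exact If `TRUE`, the p-value is computed from the exact
#'   permutation distribution over all within-row rank orderings (feasible
#'   for small `n` and `k`); otherwise from the chi-square approximation.
#' @return A `sync_test`.
#' @export
friedman_rank_test <- function(mat, exact = FALSE) {
  m <- as_matrix_complete(mat)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) {
    abort("need at least 2 participants and 2 conditions",
          class = "runsync_validation_error")
  }
  r <- t(apply(m, 1, rank_ties))
  stat_fun <- function(r) {
    rj <- colSums(r)
    a <- sum(r^2)
    cc <- n * k * (k + 1)^2 / 4
    if (a == cc) return(0)  # all rows constant
    (k - 1) * sum((rj - n * (k + 1) / 2)^2) / (a - cc)
  }
  stat <- stat_fun(r)
  if (exact) {
    perms <- all_permutations(k)
    stats_null <- friedman_null_distribution(r, perms, stat_fun)
    p <- mean(stats_null >= stat - 1e-12)
  } else {
    p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  new_sync_test("Friedman rank test", "chi-squared", stat, p,
                df = k - 1, n = n, exact = exact)
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 0
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      row <- row + 1
      out[row, ] <- append(sub[i, ], k, after = pos - 1)
    }
  }
  out
}

friedman_null_distribution <- function(r, perms, stat_fun) {
  n <- nrow(r); k <- ncol(r)
  np <- nrow(perms)
  if (np^n > 2e6) {
    abort("exact Friedman distribution infeasible for this size",
          class = "runsync_validation_error")
  }
  idx <- rep(1L, n)
  out <- numeric(np^n)
  for (s in seq_len(np^n)) {
    rp <- r
    for (i in seq_len(n)) rp[i, ] <- r[i, perms[idx[i], ]]
    out[s] <- stat_fun(rp)
    # odometer increment
    for (i in seq_len(n)) {
      idx[i] <- idx[i] + 1L
      if (idx[i] <= np) break
      idx[i] <- 1L
    }
  }
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences `x - y` are ranked by absolute value (mean ranks on ties,
#' zero differences dropped). The statistic is the positive-rank sum `W+`;
#' `Z` uses the normal approximation with tie correction and a 0.5
#' continuity correction, so swapping `x` and `y` flips the sign of `Z`
#' exactly. For fewer than `exact_limit` non-zero pairs the p-value comes
#' from the exact distribution over all `2^n` sign assignments; otherwise
#' from the normal approximation. The effect size is `r^2 = Z^2 / N` with
#' `N` the number of pairs supplied.
#'
#' @param x,y Paired numeric vectors.
#' @param exact_limit Exact enumeration below this many non-zero pairs
#'   (default 8).
#' @return A `sync_test` (fields include `w_pos` and `w_neg`).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 8) {
  if (length(x) != length(y)) {
    abort("x and y must be paired", class = "runsync_validation_error")
  }
  n_pairs <- length(x)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    abort("all differences are zero", class = "runsync_degenerate_data_error")
  }
  r <- rank_ties(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  mu <- n * (n + 1) / 4
  ties <- tie_counts(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  sigma <- sqrt(sigma2)
  dev <- w_pos - mu
  z <- if (sigma == 0) 0 else (dev - 0.5 * sign(dev)) / sigma
  exact <- n < exact_limit
  if (exact) {
    # all 2^n sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_null <- as.vector(signs %*% r)
    p <- mean(abs(w_null - mu) >= abs(dev) - 1e-12)
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  new_sync_test("Wilcoxon signed-rank test", "W+", w_pos, min(1, p),
                n = n, z = z, effect_r2 = z^2 / n_pairs, exact = exact,
                extra = list(w_pos = w_pos, w_neg = w_neg))
}

#' Mann-Whitney U test for two independent samples
#'
#' Reports `U = min(U_x, U_y)`; `Z` comes from the normal approximation
#' with tie correction and a 0.5 continuity correction applied to `U_x`,
#' so its sign indicates the direction of the first group. For small
#' samples the p-value is the exact permutation probability over all
#' `choose(n1 + n2, n1)` group labellings. Effect size
#' `r^2 = Z^2 / (n1 + n2)`.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Exact enumeration when `n1 + n2` is at most this
#'   (default 9).
#' @return A `sync_test`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 9) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) {
    abort("both groups must be non-empty", class = "runsync_validation_error")
  }
  nn <- n1 + n2
  r <- rank_ties(c(x, y))
  r1 <- sum(r[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  mu <- n1 * n2 / 2
  ties <- tie_counts(r)
  sigma <- sqrt(n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1))))
  dev <- u1 - mu
  z <- if (sigma == 0) 0 else (dev - 0.5 * sign(dev)) / sigma
  exact <- nn <= exact_limit
  if (exact) {
    combs <- utils::combn(nn, n1)
    u_null <- apply(combs, 2, function(ix) {
      sum(r[ix]) - n1 * (n1 + 1) / 2
    })
    p <- mean(abs(u_null - mu) >= abs(dev) - 1e-12)
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  new_sync_test("Mann-Whitney U test", "U", u, min(1, p),
                n = nn, z = z, effect_r2 = z^2 / nn, exact = exact,
                extra = list(u1 = u1, u2 = u2))
}

#' Bonferroni-corrected significance level
#'
#' @param familywise Familywise alpha (default 0.05).
#' @param m Number of comparisons.
#' @return The per-comparison alpha `familywise / m`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 10)  # 0.005
bonferroni_alpha <- function(familywise = 0.05, m = 1) {
  stopifnot(familywise > 0, familywise <= 1, m >= 1)
  familywise / m
}

#' Spearman rank correlation
#'
#' Pearson correlation of the mean-tied ranks, with a two-tailed p-value
#' from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A `sync_test` whose statistic is `rho`.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) {
    abort("need paired vectors of length >= 3",
          class = "runsync_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for constant input",
          class = "runsync_degenerate_data_error")
  }
  rho <- stats::cor(rank_ties(x), rank_ties(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  new_sync_test("Spearman rank correlation", "rho", rho, p, n = n)
}

#' Kolmogorov-Smirnov normality test with Lilliefors correction
#'
#' Tests departure from a normal distribution whose mean and SD are
#' estimated from the sample; the p-value therefore uses the Lilliefors
#' correction (plain KS p-values would be anticonservative with estimated
#' parameters).
#'
#' @param x Numeric sample (n >= 5).
#' @return A `sync_test` whose statistic is `D` and whose `df` slot holds
#'   the sample size, matching the `D(n)` reporting convention.
#' @export
ks_normality <- function(x) {
  n <- length(x)
  if (n < 5) {
    abort("need at least 5 observations", class = "runsync_validation_error")
  }
  if (sd(x) == 0) {
    abort("sample has zero variance", class = "runsync_degenerate_data_error")
  }
  z <- sort((x - mean(x)) / sd(x))
  cdf <- pnorm(z)
  d_plus <- max(seq_len(n) / n - cdf)
  d_minus <- max(cdf - (seq_len(n) - 1) / n)
  d <- max(d_plus, d_minus)
  p <- nortest::lillie.test(x)$p.value
  new_sync_test("Lilliefors (KS) normality test", "D", d, p, df = n, n = n)
}

#' One-way repeated-measures ANOVA with a polynomial trend contrast
#'
#' Partitions the total sum of squares of a complete participants x
#' conditions matrix into subject, condition and error strata, and tests
#' the condition effect (`df = (k-1, (n-1)(k-1))`). A single-df polynomial
#' contrast over the supplied condition scores (the 11 tempo shifts, by
#' default linear) is tested against its own subject-by-contrast error
#' term (`df = (1, n-1)`), with effect size
#' `r^2 = SS_contrast / (SS_contrast + SS_error_contrast)`.
#'
#' @param mat Numeric matrix/data frame, participants x conditions,
#'   complete; columns in the order of `scores`.
#' @param scores Numeric condition scores (e.g. `tempo_shifts()`).
#' @return A list of class `rm_anova` with `sync_test` elements `omnibus`
#'   and `contrast`.
#' @export
rm_anova_linear <- function(mat, scores = tempo_shifts()) {
  m <- as_matrix_complete(mat)
  n <- nrow(m); k <- ncol(m)
  if (length(scores) != k) {
    abort("scores must match the number of conditions",
          class = "runsync_validation_error")
  }
  gm <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_cond <- n * sum((colMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df_cond <- k - 1
  df_err <- (n - 1) * (k - 1)
  ms_err <- ss_err / df_err
  f_omni <- if (ms_err <= 0) {
    if (ss_cond == 0) 0 else Inf
  } else {
    (ss_cond / df_cond) / ms_err
  }
  p_omni <- if (is.infinite(f_omni)) 0 else
    pf(f_omni, df_cond, df_err, lower.tail = FALSE)

  w <- scores - mean(scores)
  l <- as.vector(m %*% w)        # per-subject contrast value
  ss_c <- n * mean(l)^2 / sum(w^2)
  ss_ec <- sum((l - mean(l))^2) / sum(w^2)
  f_c <- if (ss_ec == 0) {
    if (ss_c == 0) 0 else Inf
  } else {
    ss_c / (ss_ec / (n - 1))
  }
  p_c <- if (is.infinite(f_c)) 0 else pf(f_c, 1, n - 1, lower.tail = FALSE)
  r2 <- if (ss_c + ss_ec == 0) NA_real_ else ss_c / (ss_c + ss_ec)

  structure(
    list(
      omnibus = new_sync_test("RM-ANOVA condition effect", "F",
                              f_omni, p_omni, df = df_cond, n = n,
                              extra = list(df_error = df_err,
                                           ss_cond = ss_cond, ss_err = ss_err)),
      contrast = new_sync_test("RM-ANOVA linear contrast", "F",
                               f_c, p_c, df = 1, n = n, effect_r2 = r2,
                               extra = list(df_error = n - 1,
                                            ss_contrast = ss_c,
                                            ss_error_contrast = ss_ec))
    ),
    class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  print(x$omnibus); print(x$contrast)
  invisible(x)
}

#' Entrainment-basin analysis
#'
#' Summarises the tempo-entrainment score per condition (median, mean, SE)
#' and compares every shifted condition against the 0 % control with paired
#' Wilcoxon signed-rank tests, Bonferroni-corrected over the 10
#' comparisons (alpha 0.05/10 = 0.005 by default). A condition is flagged
#' when its corrected-level test is significant, with the sign of the
#' median difference recorded.
#'
#' @param metrics Tidy metric table from [score_cohort()] (needs columns
#'   `participant_id`, `shift_pct`, and the `value` column).
#' @param value Name of the score column (default `"entrainment_pct"`).
#' @param familywise_alpha Familywise alpha (default 0.05).
#' @return A list of class `basin_result` with `summary` and `comparisons`
#'   tibbles plus `bonferroni_alpha`.
#' @export
basin_analysis <- function(metrics, value = "entrainment_pct",
                           familywise_alpha = 0.05) {
  shifts <- sort(unique(metrics$shift_pct))
  if (!0 %in% shifts) {
    abort("control condition (0 % shift) missing",
          class = "runsync_validation_error")
  }
  grid <- table(metrics$participant_id, metrics$shift_pct)
  if (any(grid != 1)) {
    abort("each participant needs exactly one record per condition",
          class = "runsync_validation_error")
  }
  v <- metrics[[value]]
  summary <- metrics |>
    group_by(.data$shift_pct) |>
    summarise(median = median(.data[[value]]),
              mean = mean(.data[[value]]),
              se = sd(.data[[value]]) / sqrt(dplyr::n()),
              n = dplyr::n(), .groups = "drop")

  pid_order <- sort(unique(metrics$participant_id))
  col <- function(sh) {
    d <- metrics[metrics$shift_pct == sh, ]
    d[[value]][match(pid_order, d$participant_id)]
  }
  control <- col(0)
  m <- sum(shifts != 0)
  alpha <- if (m == 0) familywise_alpha else bonferroni_alpha(familywise_alpha, m)
  comparisons <- purrr::map_dfr(shifts[shifts != 0], function(sh) {
    test <- tryCatch(
      wilcoxon_signed_rank(col(sh), control),
      # identical columns: no evidence of any difference
      runsync_degenerate_data_error = function(e) {
        list(z = 0, p_value = 1, effect_r2 = 0)
      })
    tibble(shift_pct = sh,
           z = test$z,
           p_value = test$p_value,
           effect_r2 = test$effect_r2,
           significant = test$p_value < alpha,
           direction = sign(median(col(sh)) - median(control)))
  })
  structure(list(summary = summary, comparisons = comparisons,
                 bonferroni_alpha = alpha, value = value),
            class = "basin_result")
}

#' @export
print.basin_result <- function(x, ...) {
  cat(sprintf("<basin_result> %s vs control, Bonferroni alpha = %.4g\n",
              x$value, x$bonferroni_alpha))
  flagged <- x$comparisons$shift_pct[x$comparisons$significant]
  cat("flagged conditions:",
      if (length(flagged)) paste(sprintf("%+.1f%%", flagged), collapse = " ")
      else "none", "\n")
  invisible(x)
}
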