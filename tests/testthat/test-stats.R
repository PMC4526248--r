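test_that("Friedman statistic matches hand computation and base R", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- friedman_rank_test(m)
  expect_equal(res$statistic, 6)       # 12/(nk(k+1)) * sum(R^2) - 3n(k+1)
  expect_equal(res$df, 2)

  same <- matrix(5, 4, 3)
  res0 <- friedman_rank_test(same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # cross-check statistic (with ties) against stats::friedman.test
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(sample(1:5, 24, replace = TRUE), nrow = 6)
    ours <- friedman_rank_test(m)
    base <- suppressWarnings(stats::friedman.test(m))
    expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, unname(base$p.value), tolerance = 1e-12)
  }
})

test_that("exact Friedman p agrees with full within-row enumeration", {
  set.seed(12)
  m <- matrix(rnorm(12), nrow = 4, ncol = 3)
  res <- friedman_rank_test(m, exact = TRUE)

  # oracle: enumerate all column orderings per row independently
  perms <- perms_of(1:3)
  stat_of <- function(mm) {
    r <- t(apply(mm, 1, rank))
    rj <- colSums(r)
    n <- nrow(mm); k <- ncol(mm)
    12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  }
  combos <- expand.grid(rep(list(seq_along(perms)), 4))
  null_stats <- apply(combos, 1, function(ix) {
    mm <- m
    for (i in 1:4) mm[i, ] <- m[i, perms[[ix[i]]]]
    stat_of(mm)
  })
  p_oracle <- mean(null_stats >= stat_of(m) - 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank is directional, antisymmetric, exact for small n", {
  x <- 1:10
  y <- x + 3
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$w_pos, 0)  # every difference negative
  expect_lt(res$z, 0)

  swapped <- wilcoxon_signed_rank(y, x)
  expect_equal(swapped$z, -res$z)
  expect_equal(swapped$p_value, res$p_value)

  # n = 6: exact p equals brute force over all 2^6 sign patterns
  set.seed(2)
  a <- rnorm(6); b <- rnorm(6)
  res6 <- wilcoxon_signed_rank(a, b)
  expect_true(res6$exact)
  d <- a - b
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  w_null <- as.vector(signs %*% r)
  mu <- 6 * 7 / 4
  obs <- sum(r[d > 0])
  p_oracle <- mean(abs(w_null - mu) >= abs(obs - mu) - 1e-12)
  expect_equal(res6$p_value, p_oracle)
  # statistic agrees with base R's V
  expect_equal(res6$w_pos,
               unname(suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))$statistic))

  expect_error(wilcoxon_signed_rank(1:4, 1:4),
               class = "runsync_degenerate_data_error")
})

test_that("exact signed-rank p matches enumeration for all small sizes", {
  set.seed(40)
  for (n in 5:7) {
    for (rep in 1:5) {
      x <- sample(1:10, n, replace = TRUE)
      y <- sample(1:10, n, replace = TRUE)
      d <- x - y
      if (all(d == 0)) next
      res <- wilcoxon_signed_rank(x, y)
      dd <- d[d != 0]; nn <- length(dd)
      r <- rank(abs(dd))
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), nn)))
      w_null <- as.vector(signs %*% r)
      mu <- nn * (nn + 1) / 4
      obs <- sum(r[dd > 0])
      expect_equal(res$p_value,
                   mean(abs(w_null - mu) >= abs(obs - mu) - 1e-12))
    }
  }
})

test_that("Mann-Whitney U uses the min convention with exact small-sample p", {
  res <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))
  expect_equal(res$statistic, 0)  # complete separation

  x <- c(3, 1, 4, 1); y <- c(5, 9, 2, 6)
  expect_equal(mann_whitney_u(x, y)$statistic,
               mann_whitney_u(y, x)$statistic)
  expect_equal(mann_whitney_u(x, y)$z, -mann_whitney_u(y, x)$z)

  # 4 vs 4: exact p equals enumeration over C(8,4) labellings
  res8 <- mann_whitney_u(x, y)
  expect_true(res8$exact)
  r <- rank(c(x, y))
  mu <- 4 * 4 / 2
  u_obs <- sum(r[1:4]) - 4 * 5 / 2
  u_null <- apply(utils::combn(8, 4), 2, function(ix) sum(r[ix]) - 10)
  expect_equal(res8$p_value,
               mean(abs(u_null - mu) >= abs(u_obs - mu) - 1e-12))

  # statistic cross-check against base R (W is U of the first group)
  set.seed(77)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(4)
    ours <- mann_whitney_u(a, b)
    base <- suppressWarnings(stats::wilcox.test(a, b))
    expect_equal(min(unname(base$statistic),
                     5 * 4 - unname(base$statistic)), ours$statistic)
  }
})

test_that("effect sizes follow the r^2 = Z^2 / N reporting convention", {
  x <- c(9, 8, 11, 14, 6, 7, 12, 13, 10)
  y <- c(1, 3, 2, 5, 4, 6.5, 2.5, 3.5, 1.5)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$effect_r2, w$z^2 / 9)
  u <- mann_whitney_u(x, y)
  expect_equal(u$effect_r2, u$z^2 / 18)
})

test_that("Bonferroni correction divides the familywise level", {
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(1.0, 4), 0.25)
})

test_that("Spearman correlation matches the rank formula and base R", {
  expect_equal(spearman_rho(1:8, (1:8)^3)$statistic, 1)
  expect_equal(spearman_rho(1:8, -(1:8))$statistic, -1)
  expect_equal(spearman_rho(1:8, (1:8)^3)$p_value, 0)

  # n = 5, no ties: 1 - 6 sum(d^2) / (n (n^2 - 1))
  x <- c(3, 1, 4, 5, 2); y <- c(2, 1, 5, 3, 4)
  d2 <- sum((rank(x) - rank(y))^2)
  res <- spearman_rho(x, y)
  expect_equal(res$statistic, 1 - 6 * d2 / (5 * 24))
  expect_equal(res$statistic,
               unname(stats::cor.test(x, y, method = "spearman")$estimate))

  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "runsync_degenerate_data_error")
})

test_that("Lilliefors KS test matches nortest's D and is calibrated", {
  set.seed(6)
  x <- rnorm(60)
  res <- ks_normality(x)
  ref <- nortest::lillie.test(x)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value)

  # normal data rarely rejected; uniform data reliably rejected
  normal_p <- vapply(1:40, function(s) {
    set.seed(s); ks_normality(rnorm(1000))$p_value
  }, numeric(1))
  expect_gte(mean(normal_p > 0.05), 0.95)
  uniform_p <- vapply(1:40, function(s) {
    set.seed(s); ks_normality(runif(200))$p_value
  }, numeric(1))
  expect_gte(mean(uniform_p < 0.05), 0.95)

  expect_error(ks_normality(rep(2, 10)),
               class = "runsync_degenerate_data_error")
})

test_that("repeated-measures ANOVA matches a direct SS decomposition and aov", {
  set.seed(14)
  m <- matrix(rnorm(15, mean = rep(c(0, 1, 3), each = 5)), nrow = 5)
  scores <- c(-1, 0, 1)
  res <- rm_anova_linear(m, scores)

  # oracle: explicit sums of squares
  gm <- mean(m)
  ss_subj <- 3 * sum((rowMeans(m) - gm)^2)
  ss_cond <- 5 * sum((colMeans(m) - gm)^2)
  ss_err <- sum((m - gm)^2) - ss_subj - ss_cond
  f_oracle <- (ss_cond / 2) / (ss_err / 8)
  expect_equal(res$omnibus$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(res$omnibus$df, 2)
  expect_equal(res$omnibus$df_error, 8)

  # cross-check against aov with an Error stratum
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(1:5, 3)),
                   cond = factor(rep(1:3, each = 5)))
  fit <- summary(stats::aov(y ~ cond + Error(subj/cond), data = df))
  f_aov <- fit[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(res$omnibus$statistic, f_aov, tolerance = 1e-10)

  # linear contrast equals a one-sample t test on per-subject slopes
  l <- as.vector(m %*% (scores - mean(scores)))
  t_or <- unname(stats::t.test(l)$statistic)
  expect_equal(res$contrast$statistic, t_or^2, tolerance = 1e-10)
  expect_equal(res$contrast$p_value, stats::t.test(l)$p.value,
               tolerance = 1e-10)

  # degenerate shapes
  lin <- matrix(rep(scores, each = 4), nrow = 4)
  expect_equal(rm_anova_linear(lin, scores)$contrast$effect_r2, 1)
  const <- matrix(rep(1:4, 3), nrow = 4)
  expect_equal(rm_anova_linear(const, scores)$omnibus$statistic, 0)
})

test_that("basin analysis flags exactly the Bonferroni-significant conditions", {
  # identical scores everywhere: nothing can be flagged
  flat <- expand.grid(participant_id = paste0("P", 1:8),
                      shift_pct = tempo_shifts())
  flat$entrainment_pct <- 50
  res <- basin_analysis(flat)
  expect_equal(res$bonferroni_alpha, 0.005)
  expect_false(any(res$comparisons$significant))

  # flags respect elementwise dominance: strictly worse columns stay flagged
  set.seed(8)
  grid <- expand.grid(participant_id = paste0("P", 1:12),
                      shift_pct = tempo_shifts())
  grid$entrainment_pct <- 70 + rnorm(nrow(grid), 0, 4)
  sel_a <- grid$shift_pct == 2.5
  grid$entrainment_pct[sel_a] <- grid$entrainment_pct[sel_a] - 30
  grid$entrainment_pct[grid$shift_pct == 3] <-
    grid$entrainment_pct[sel_a] - 5  # dominated by the 2.5 column
  res2 <- basin_analysis(grid)
  cmp <- res2$comparisons
  expect_true(cmp$significant[cmp$shift_pct == 2.5])
  expect_true(cmp$significant[cmp$shift_pct == 3])
  expect_equal(cmp$direction[cmp$shift_pct == 3], -1)

  # incomplete grids are rejected
  expect_error(basin_analysis(grid[-1, ]), class = "runsync_validation_error")
})

test_that("result objects tidy into one-row summaries", {
  res <- mann_whitney_u(rnorm(10), rnorm(10))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("statistic", "p_value", "z", "effect_r2") %in% names(td)))

  m <- matrix(rnorm(33), nrow = 3)
  ta <- tidy(rm_anova_linear(m, scores = tempo_shifts()))
  expect_equal(ta$term, c("condition", "linear_contrast"))

  flat <- expand.grid(participant_id = paste0("P", 1:6),
                      shift_pct = tempo_shifts())
  flat$entrainment_pct <- runif(nrow(flat), 40, 60)
  tb <- tidy(basin_analysis(flat))
  expect_equal(nrow(tb), 11)
  expect_equal(nrow(glance(basin_analysis(flat))), 1)
})
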