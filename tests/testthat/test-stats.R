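two_group_tbl <- function(a, b, labels = c("A", "B")) {
  tibble::tibble(value = c(a, b),
                 grp = rep(labels, c(length(a), length(b))))
}

test_that("identical groups give a zero statistic and p = 1", {
  x <- c(1, 2, 3, 4, 5)
  tt <- t_test_groups(two_group_tbl(x, x), value, grp)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  expect_identical(tt$tier, "ns")
})

test_that("swapping groups flips the sign and preserves p", {
  set.seed(1)
  a <- rnorm(8)
  b <- rnorm(8, 1)
  t1 <- t_test_groups(two_group_tbl(a, b), value, grp)
  t2 <- t_test_groups(two_group_tbl(b, a), value, grp)
  expect_equal(t1$statistic, -t2$statistic)
  expect_equal(t1$p_value, t2$p_value)
  # pooled df for student variant
  expect_equal(t1$df, 14)
  w <- t_test_groups(two_group_tbl(a, b), value, grp, variant = "welch")
  expect_lt(abs(w$p_value - t1$p_value), 0.05)
})

test_that("a 10-SD separation is overwhelmingly significant, per permutations", {
  set.seed(2)
  a <- rnorm(8, 0, 1)
  b <- rnorm(8, 10, 1)
  tt <- t_test_groups(two_group_tbl(a, b), value, grp)
  expect_lt(tt$p_value, 1e-6)
  expect_identical(tt$tier, "***")
  # permutation oracle: no relabeling reaches the observed |t|
  v <- c(a, b)
  obs <- abs(tt$statistic)
  n_perm <- 1e5
  exceed <- 0L
  pooled_t <- function(x, y) {
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  }
  set.seed(3)
  for (k in seq_len(n_perm)) {
    idx <- sample.int(16, 8)
    if (abs(pooled_t(v[idx], v[-idx])) >= obs) exceed <- exceed + 1L
  }
  expect_lt((exceed + 1) / (n_perm + 1), 1e-4)
})

test_that("input validation rejects tiny or non-finite samples", {
  expect_error(t_test_groups(two_group_tbl(1, c(2, 3)), value, grp),
               "at least 2")
  expect_error(t_test_groups(two_group_tbl(c(1, NA), c(2, 3)), value, grp),
               "finite")
  expect_error(
    t_test_groups(tibble::tibble(value = 1:6, grp = rep(c("A", "B", "C"), 2)),
                  value, grp),
    "exactly two")
})

test_that("identical groups yield F = 0 and all Tukey p = 1", {
  x <- c(3, 1, 4, 1, 5)
  df <- tibble::tibble(value = rep(x, 3),
                       grp = rep(c("A", "B", "C"), each = 5))
  at <- anova_tukey(df, value, grp)
  expect_equal(glance(at)$statistic, 0)
  expect_equal(tidy(at)$p_adjusted, rep(1, 3))
  expect_true(all(tidy(at)$tier == "ns"))
})

test_that("three-group fixture: Tukey separates the shifted pair, matching a max-t permutation oracle", {
  # textbook-style fixture with known means and spread: groups A and B share
  # the same shape shifted by a negligible 0.1, C sits 6 units away
  n <- 8
  a <- seq(-1.75, 1.75, by = 0.5)
  b <- a + 0.1
  c_ <- a + 6
  df <- tibble::tibble(value = c(a, b, c_),
                       grp = rep(c("A", "B", "C"), each = n))
  at <- anova_tukey(df, value, grp)
  tk <- tidy(at)
  p_ac <- tk$p_adjusted[tk$contrast %in% c("C-A", "A-C")]
  p_ab <- tk$p_adjusted[tk$contrast %in% c("B-A", "A-B")]
  expect_lt(p_ac, 0.001)
  expect_gt(p_ab, 0.5)
  # permutation oracle: null distribution of the max pairwise |t|
  v <- c(a, b, c_)
  obs_ab <- abs(mean(a) - mean(b)) / sqrt(2 * mean(c(var(a), var(b), var(c_))) / n)
  set.seed(8)
  n_perm <- 1e5
  # vectorized resampling: each column is one permuted cohort split 8/8/8
  perm <- array(vapply(seq_len(n_perm), function(k) v[sample.int(3 * n)],
                       numeric(3 * n)), c(n, 3, n_perm))
  gm <- colMeans(perm)                       # 3 x n_perm group means
  gv <- (colSums(perm^2) - n * gm^2) / (n - 1)
  s2 <- colMeans(gv)                         # pooled variance per perm
  spread <- apply(gm, 2, function(m) max(m) - min(m))
  perm_stats <- spread / sqrt(2 * s2 / n)
  # adjusted p of the near-null pair by the max-t (single-step) method
  p_ab_perm <- mean(perm_stats >= obs_ab)
  expect_gt(p_ab_perm, 0.3)
  expect_lt(abs(p_ab_perm - p_ab), 0.2)
  # the shifted pair exceeds every resampled max-t
  obs_ac <- abs(mean(a) - mean(c_)) /
    sqrt(2 * mean(c(var(a), var(b), var(c_))) / n)
  expect_lt(mean(perm_stats >= obs_ac) + 1 / n_perm, 0.005)
})

test_that("with two groups Tukey reduces to the pooled t-test", {
  set.seed(9)
  df <- two_group_tbl(rnorm(6, 0), rnorm(9, 0.8))
  at <- anova_tukey(df, value, grp)
  tt <- t_test_groups(df, value, grp)
  expect_equal(tidy(at)$p_adjusted, tt$p_value, tolerance = 1e-6)
  expect_equal(abs(tidy(at)$statistic), abs(tt$statistic), tolerance = 1e-9)
})

test_that("Tukey-adjusted p never undercuts the raw pairwise p", {
  set.seed(10)
  df <- tibble::tibble(value = rnorm(32, rep(c(0, 0.5, 1, 1.5), each = 8)),
                       grp = rep(c("A", "B", "C", "D"), each = 8))
  at <- anova_tukey(df, value, grp)
  tk <- tidy(at)
  for (i in seq_len(nrow(tk))) {
    sub <- df[df$grp %in% c(tk$group1[i], tk$group2[i]), ]
    raw <- t_test_groups(sub, value, grp)$p_value
    expect_gte(tk$p_adjusted[i], raw - 1e-9)
  }
})

test_that("ANOVA F is shift-invariant and scale-invariant", {
  set.seed(11)
  df <- tibble::tibble(value = rnorm(24, rep(c(0, 1, 2), each = 8)),
                       grp = rep(c("A", "B", "C"), each = 8))
  f0 <- glance(anova_tukey(df, value, grp))$statistic
  df2 <- dplyr::mutate(df, value = value + 100)
  df3 <- dplyr::mutate(df, value = value * 7)
  expect_equal(glance(anova_tukey(df2, value, grp))$statistic, f0)
  expect_equal(glance(anova_tukey(df3, value, grp))$statistic, f0)
})

test_that("a variance ratio above 10 warns without failing", {
  set.seed(12)
  df <- two_group_tbl(rnorm(8, 0, 0.1), rnorm(8, 0, 10))
  expect_warning(anova_tukey(df, value, grp), "variance ratio")
})

test_that("significance tiers follow the three thresholds", {
  expect_identical(significance_tier(c(0.2, 0.049, 0.009, 0.0009, NA)),
                   c("ns", "*", "**", "***", NA_character_))
})

test_that("cohort_report summarizes groups and tolerates a single group", {
  set.seed(13)
  tbl <- tibble::tibble(
    dye_label = rep(c("40 kDa", "2 MDa"), each = 8),
    time_h = 24,
    area_percent = c(rnorm(8, 10, 1), rnorm(8, 3, 1))
  )
  rep_ <- cohort_report(tbl)
  expect_identical(nrow(rep_$summary), 2L)
  expect_equal(rep_$summary$sem, rep_$summary$sd / sqrt(rep_$summary$n))
  expect_identical(nrow(rep_$dye_contrasts), 1L)
  expect_identical(nrow(rep_$time_contrasts), 0L)
  # single group: report, no contrasts, no error
  rep1 <- cohort_report(tbl[tbl$dye_label == "2 MDa", ])
  expect_identical(nrow(rep1$summary), 1L)
  expect_identical(nrow(rep1$dye_contrasts), 0L)
  # shuffling rows changes nothing
  rep2 <- cohort_report(tbl[sample.int(nrow(tbl)), ])
  expect_equal(rep2$summary, rep_$summary)
  expect_equal(rep2$dye_contrasts$p_adjusted, rep_$dye_contrasts$p_adjusted)
  expect_error(cohort_report(dplyr::select(tbl, -time_h)), "must contain")
})
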