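test_that("MAD-median rule matches the printed formula and its oracle", {
  expect_false(any(mad_median_outliers(c(1, 1, 1, 1))$outlier))
  v <- c(1, 2, 3, 4, 5, 100)
  verdict <- mad_median_outliers(v)
  expect_identical(verdict$outlier, oracle_mad_mask(v))
  expect_true(verdict$outlier[6])
  expect_false(any(verdict$outlier[1:5]))
  # scale equivariance
  set.seed(1)
  x <- rnorm(40)
  expect_identical(mad_median_outliers(x)$outlier,
                   mad_median_outliers(10 * x)$outlier)
  # degenerate MAD = 0: only values != median flagged
  expect_identical(mad_median_outliers(c(2, 2, 2, 2, 7))$outlier,
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(mad_median_outliers(c(1, 2)), "at least 3")
})

test_that("within-subject permutation ANOVA reproduces aov F statistics", {
  set.seed(42)
  d <- expand.grid(subject = factor(1:10), A = factor(1:2), B = factor(1:3))
  d$y <- rnorm(nrow(d)) + as.numeric(d$A) * 0.4 + rep(rnorm(10), 6)
  r <- perm_anova_within(d, "y", c("A", "B"), n_perm = 200, seed = 1)
  a <- summary(stats::aov(y ~ A * B + Error(subject / (A * B)), data = d))
  expect_equal(r$statistic[r$effect == "A"],
               a[["Error: subject:A"]][[1]]$F[1])
  expect_equal(r$statistic[r$effect == "B"],
               a[["Error: subject:B"]][[1]]$F[1])
  expect_equal(r$statistic[r$effect == "A:B"],
               a[["Error: subject:A:B"]][[1]]$F[1])
  expect_equal(r$df1, c(1, 2, 2))
  expect_equal(r$df2, c(9, 18, 18))

  # 2x2x9 design: every effect matches aov
  d3 <- expand.grid(subject = factor(1:6), L = factor(1:2),
                    S = factor(1:2), P = factor(1:9))
  set.seed(7)
  d3$y <- rnorm(nrow(d3))
  r3 <- perm_anova_within(d3, "y", c("L", "S", "P"), n_perm = 100, seed = 2)
  a3 <- summary(stats::aov(y ~ L * S * P + Error(subject / (L * S * P)),
                           data = d3))
  for (eff in c("L", "S", "P", "L:S", "L:P", "S:P", "L:S:P")) {
    stratum <- paste0("Error: subject:", gsub(":", ":", eff))
    expect_equal(r3$statistic[r3$effect == eff],
                 a3[[stratum]][[1]]$F[1],
                 tolerance = 1e-8, label = eff)
  }
})

test_that("permutation ANOVA degenerate and boundary behaviour", {
  # all cells identical within each subject -> p ~ 1 for every effect
  d <- expand.grid(subject = factor(1:8), A = factor(1:2), B = factor(1:3))
  d$y <- rep(rnorm(8), 6)
  r <- perm_anova_within(d, "y", c("A", "B"), n_perm = 200, seed = 3)
  expect_true(all(r$p_value > 0.99))
  # a huge effect reaches the attainable minimum p = 1/(n_perm + 1)
  d2 <- expand.grid(subject = factor(1:12), A = factor(1:2))
  d2$y <- rnorm(nrow(d2), sd = 0.01) + 10 * (as.numeric(d2$A) - 1)
  r2 <- perm_anova_within(d2, "y", "A", n_perm = 999, seed = 4)
  expect_equal(r2$p_value, 1 / 1000)
  # unbalanced designs error
  expect_error(perm_anova_within(d[-1, ], "y", c("A", "B")), "unbalanced")
  expect_warning(perm_anova_within(d, "y", c("A", "B"), n_perm = 50,
                                   seed = 1), "n_perm")
})

test_that("row-wise permutation preserves each subject's multiset of
           values", {
  set.seed(5)
  Y <- matrix(rnorm(30), 5, 6)
  Yp <- gaitalpha:::.permute_within_rows(Y)
  expect_equal(rowSums(Yp), rowSums(Y))
  for (i in 1:5) expect_setequal(Yp[i, ], Y[i, ])
})

test_that("sign-flipping paired test: identity, antisymmetry, and errors", {
  expect_equal(perm_paired_t(1:10, 1:10)$p_value, 1)
  set.seed(6)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(perm_paired_t(x, y, 1000, seed = 8)$p_value,
               perm_paired_t(y, x, 1000, seed = 8)$p_value)
  expect_equal(perm_paired_t(x, y, 1000, seed = 8)$statistic, mean(x - y))
  expect_error(perm_paired_t(1, 2), "at least 2")
})

test_that("permutation p-values are stable across seeds", {
  set.seed(11)
  d <- expand.grid(subject = factor(1:20), A = factor(1:2))
  d$y <- rnorm(nrow(d)) + 0.55 * (as.numeric(d$A) - 1) + rep(rnorm(20), 2)
  ps <- vapply(1:10, function(s) {
    perm_anova_within(d, "y", "A", n_perm = 5000, seed = s)$p_value
  }, 0)
  expect_lt(diff(range(ps)), 0.01)
})

test_that("BY-FDR matches the brute-force step-up oracle and never beats
           BH", {
  expect_equal(fdr_adjust(0.03)$p_adjusted, 0.03)  # m = 1 -> unchanged
  expect_true(all(fdr_adjust(rep(0, 5))$significant))
  set.seed(13)
  for (i in 1:5) {
    p <- runif(40)^2
    got <- fdr_adjust(p)
    expect_equal(got$p_adjusted, oracle_by_adjust(p))
    expect_lte(sum(got$significant), oracle_bh_discoveries(p))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("epoch grouping applies the exclusion and grouping rules", {
  ep <- tibble::tibble(
    subject = rep(1:2, each = 50),
    alpha_power = rep(1, 100),
    outlier = rep(c(FALSE, TRUE), c(95, 5)),
    saccade_count = rep(c(0, 1, 2, 5, 7), 20),
    blink_count = rep(c(0, 1, 2, 0, 1), 20),
    pupil = seq(0.5, 5, length.out = 100)
  )
  g <- suppressWarnings(group_epochs_by_covariate(ep, "saccade_count"))
  expect_true(all(as.integer(as.character(g$group)) <= 4))
  # epochs with exactly 5 (and more) saccades are excluded
  expect_equal(sum(g$n_epochs),
               sum(!ep$outlier & ep$saccade_count <= 4))
  gb <- suppressWarnings(group_epochs_by_covariate(ep, "blink_count"))
  expect_equal(sum(gb$n_epochs), sum(!ep$outlier & ep$blink_count <= 1))
  gq <- group_epochs_by_covariate(ep, "pupil_quintile")
  sizes <- tapply(gq$n_epochs, gq$subject, function(x) diff(range(x)))
  expect_true(all(sizes <= 1))  # equal-count partition
})

test_that("single-covariate-level epochs give a null group comparison", {
  ep <- tibble::tibble(
    subject = rep(1:6, each = 40),
    alpha_power = rnorm(240, mean = 5),
    outlier = FALSE,
    saccade_count = 0L,
    blink_count = 0L,
    pupil = rnorm(240)
  )
  g <- suppressWarnings(group_epochs_by_covariate(ep, "saccade_count"))
  expect_equal(nlevels(droplevels(g$group)), 1)
})

test_that("frequency-wise scan returns an empty mask for identical
           conditions", {
  grid <- expand.grid(subject = 1:6, lighting = "light",
                      speed = c("still", "slow", "normal"),
                      freq = 2:50)
  grid$power <- rep(rnorm(6 * 49), times = 1)[
    as.integer(interaction(grid$subject, grid$freq))]
  scan <- frequencywise_speed_scan(tibble::as_tibble(grid), n_perm = 200,
                                   seed = 5)
  expect_equal(nrow(scan), 49)
  expect_false(any(scan$significant))
})
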