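# The statistical battery.

# build a 5-point sample with an exact t statistic against mu0 = 0
sample_with_t <- function(t, n = 5) {
  b <- as.numeric(scale(seq_len(n)))        # mean 0, sd 1
  b + t / sqrt(n)
}

test_that("one-sample t reproduces the printed t -> p pairs at df = 4", {
  pairs <- rbind(c(2.06, 0.108), c(1.89, 0.132), c(3.10, 0.036),
                 c(2.60, 0.060), c(2.50, 0.067), c(2.57, 0.062),
                 c(3.07, 0.037), c(3.81, 0.019))
  for (i in seq_len(nrow(pairs))) {
    res <- one_sample_t(sample_with_t(pairs[i, 1]), 0)
    expect_equal(res$statistic, pairs[i, 1], tolerance = 1e-9)
    expect_equal(res$df, 4)
    expect_equal(round(res$p_value, 3), pairs[i, 2])
  }
  # degenerate: all values at mu0
  res <- one_sample_t(rep(2, 5), 2)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("critical_z matches the stated threshold correspondence", {
  expect_equal(round(critical_z(0.001), 2), 3.09)
  expect_equal(critical_z(0.5), 0)
  expect_equal(round(critical_z(0.025), 2), 1.96)
})

test_that("Dunnett distribution: exact at m = 1, frozen scipy oracle at m = 3", {
  # m = 1 reduces to an ordinary two-sided t probability
  for (q in c(1, 2.1, 3)) for (df in c(5, 20))
    expect_equal(1 - pdunnett(q, 1, df), 2 * pt(-q, df), tolerance = 1e-10)

  # independent-groups many-to-one dataset; statistics and adjusted p values
  # computed with scipy.stats.dunnett (1.17.1) and frozen (QMC jitter ~1e-4)
  tstats <- c(5.59107464, 0.86016533, -4.40834731)
  p_oracle <- c(5.84e-05, 0.725876, 7.34e-04)
  df <- 20
  p_mine <- vapply(tstats, function(t) 1 - pdunnett(abs(t), 3, df), numeric(1))
  expect_equal(p_mine[2], p_oracle[2], tolerance = 2e-3)
  expect_equal(p_mine[c(1, 3)], p_oracle[c(1, 3)], tolerance = 0.25)  # relative-scale tails
  expect_lt(max(abs(p_mine - p_oracle)), 2e-3)
})

test_that("RM ANOVA with Dunnett: trivial cases and monotonicity", {
  m <- matrix(rep(c(3, 5, 4, 6), each = 4), nrow = 4)  # identical rows per bin
  m_id <- matrix(5, 4, 4)                               # all bins identical
  res <- rm_anova_dunnett(m_id, baseline_bin = 1)
  expect_equal(res$anova$statistic, 0)
  expect_equal(res$anova$p_value, 1)
  expect_true(all(res$comparisons$p_adj == 1))

  set.seed(2)
  dat <- matrix(rnorm(6 * 5, mean = rep(c(0, 0.5, 1, 0.2, 0), each = 6)), 6, 5)
  res <- rm_anova_dunnett(dat, baseline_bin = 1)
  expect_equal(res$anova$df, c(4, 20))
  # adjusted p >= raw p, all in [0, 1]
  expect_true(all(res$comparisons$p_adj >= res$comparisons$p_raw - 1e-12))
  expect_true(all(res$comparisons$p_adj >= 0 & res$comparisons$p_adj <= 1))
  # omnibus F agrees with stats::aov on the same data (independent route)
  d <- data.frame(y = as.vector(dat),
                  subj = factor(rep(1:6, 5)), bin = factor(rep(1:5, each = 6)))
  a <- summary(aov(y ~ bin + Error(subj), data = d))
  f_aov <- a[["Error: Within"]][[1]]["bin", "F value"]
  expect_equal(res$anova$statistic, f_aov, tolerance = 1e-9)
})

test_that("two-way ANOVA matches hand-worked sums of squares; Sidak gating", {
  # constructed 2x2 with 3 replicates per cell
  d <- expand.grid(f1 = c("a", "b"), f2 = c("x", "y"), rep = 1:3)
  mu <- c(a.x = 10, b.x = 12, a.y = 11, b.y = 17)
  eps <- c(-1, 0, 1)
  d$y <- mu[paste(d$f1, d$f2, sep = ".")] + eps[d$rep]
  # hand computation: cell means as above, residual SS = 8 cells? ->
  # each cell has residuals (-1, 0, 1): SSE = 4 cells * 2 = 8, df = 8
  res <- two_way_anova_sidak(d, comparisons = list(
    list(within = "y", levels = c("a", "b")),
    list(within = "x", levels = c("a", "b"))))
  sse <- res$anova[res$anova$effect == "Residuals", ]
  expect_equal(sse$df, 8)
  gm <- mean(d$y)
  ss_f1 <- 6 * sum((tapply(d$y, d$f1, mean) - gm)^2)
  ss_f2 <- 6 * sum((tapply(d$y, d$f2, mean) - gm)^2)
  expect_equal(res$anova$F[res$anova$effect == "f1"], (ss_f1 / 1) / 1,
               tolerance = 1e-9)
  expect_equal(res$anova$F[res$anova$effect == "f2"], (ss_f2 / 1) / 1,
               tolerance = 1e-9)
  expect_true(res$gate_open)
  expect_equal(nrow(res$posthoc), 2)
  expect_equal(res$posthoc$p_sidak, 1 - (1 - res$posthoc$p_raw)^2)

  # zero-effect data: gate stays closed, no post hoc
  set.seed(1)
  d0 <- expand.grid(f1 = c("a", "b"), f2 = c("x", "y"), rep = 1:10)
  d0$y <- rnorm(nrow(d0))
  res0 <- two_way_anova_sidak(d0, comparisons = list(
    list(within = "x", levels = c("a", "b"))))
  if (!res0$gate_open) expect_null(res0$posthoc)
  # m = 1: adjusted equals raw
  res1 <- two_way_anova_sidak(d, comparisons = list(
    list(within = "y", levels = c("a", "b"))))
  expect_equal(res1$posthoc$p_sidak, res1$posthoc$p_raw)
})

test_that("chi-square contingency: closed form, identity and pairwise modes", {
  res <- chi_square_contingency(rbind(c(10, 20), c(20, 10)))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)  # 6.667
  expect_equal(res$df, 1)
  expect_equal(res$p_value,
               chisq.test(rbind(c(10, 20), c(20, 10)), correct = FALSE)$p.value)
  # identical row distributions -> statistic 0, p 1
  res0 <- chi_square_contingency(rbind(c(5, 10), c(10, 20)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # three periods: omnibus + 3 pairwise results
  tab <- cbind(p1 = c(8, 12, 30), p2 = c(10, 10, 30), p3 = c(20, 5, 25))
  pw <- chi_square_contingency(tab, pairwise = TRUE)
  expect_length(pw$pairwise, 3)
  expect_equal(pw$omnibus$df, 4)
})

test_that("ROUT flags gross outliers and only those", {
  tight <- c(9.8, 10.1, 10.0, 9.9, 10.2)
  expect_false(any(rout_outliers(tight)))
  with_out <- c(tight, 100)
  mask <- rout_outliers(with_out)
  expect_identical(which(mask), 6L)
  expect_error(rout_outliers(c(1, 2, 3, 4)), "at least 5")
  # flagging survives at Q = 0.005 across noise draws
  set.seed(42)
  hits <- vapply(1:200, function(i) {
    v <- c(rnorm(9, 10, 0.2), 100)
    m <- rout_outliers(v, Q = 0.005)
    m[10] && sum(m) == 1
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})
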