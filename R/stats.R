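# Statistical battery applied to the pipeline outputs.

test_result <- function(test, statistic, df, p_value, method = NA_character_,
                        adjusted = FALSE, ...) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, adjusted = adjusted, method = method, ...),
            class = "pe_test_result")
}

#' @export
print.pe_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g%s\n", x$test,
              x$statistic, paste(x$df, collapse = ", "), x$p_value,
              if (isTRUE(x$adjusted)) sprintf(" (adjusted, %s)", x$method) else ""))
  invisible(x)
}

#' One-sample t test (two-tailed)
#'
#' @param values Numeric sample.
#' @param mu0 Null mean.
#' @return A test result: `statistic` (t), `df` (n - 1), `p_value`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  n <- length(values)
  stopifnot(n >= 2)
  s <- stats::sd(values)
  t <- if (s == 0) 0 else (mean(values) - mu0) / (s / sqrt(n))
  p <- if (s == 0 && mean(values) == mu0) 1 else 2 * stats::pt(-abs(t), n - 1)
  test_result("one_sample_t", t, n - 1, p)
}

#' Critical value of the standard normal distribution
#'
#' `critical_z(0.001)` is 3.09 (2 dp), the per-bin response threshold.
#'
#' @param alpha Upper-tail probability.
#' @return `qnorm(1 - alpha)`.
#' @export
critical_z <- function(alpha) stats::qnorm(1 - alpha)

#' Distribution function of the two-sided Dunnett many-to-one statistic
#'
#' `P(max_i |T_i| <= q)` for `m` equicorrelated (rho = 0.5, the equal-n
#' many-to-one case) t statistics sharing one variance estimate with `df`
#' degrees of freedom. Evaluated by nested numerical integration over the
#' common control variate and the scale mixture.
#'
#' @param q Quantile (>= 0).
#' @param m Number of comparisons.
#' @param df Error degrees of freedom.
#' @return Probability.
#' @export
pdunnett <- function(q, m, df) {
  if (q <= 0) return(0)
  inner <- function(s) {
    g <- function(z0)
      stats::dnorm(z0) *
        (stats::pnorm(z0 + sqrt(2) * q * s) - stats::pnorm(z0 - sqrt(2) * q * s))^m
    stats::integrate(g, -8.5, 8.5, rel.tol = 1e-10)$value
  }
  # s = sqrt(chi2_df / df); integrate over its density
  f <- function(s)
    vapply(s, function(si)
      2 * (df / 2)^(df / 2) / gamma(df / 2) * si^(df - 1) *
        exp(-df * si^2 / 2) * inner(si), numeric(1))
  stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
}

#' Repeated-measures one-way ANOVA with Dunnett's test vs a baseline bin
#'
#' Within-subject one-way ANOVA across bins (columns), error term the
#' subject x bin interaction, followed by Dunnett many-to-one comparisons of
#' every bin against the baseline bin on the multivariate-t reference
#' (no sphericity correction unless requested).
#'
#' @param mat Numeric matrix, subjects x bins.
#' @param baseline_bin Column index of the baseline bin.
#' @param gg_correction Apply the Greenhouse-Geisser epsilon to the omnibus F.
#' @return List: `anova` (test result for the omnibus F) and `comparisons`
#'   (data frame `bin`, `t`, `p_raw`, `p_adj`).
#' @export
rm_anova_dunnett <- function(mat, baseline_bin = 1, gg_correction = FALSE) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  stopifnot(n >= 2, k >= 2, baseline_bin %in% seq_len(k))
  grand <- mean(mat)
  col_m <- colMeans(mat); row_m <- rowMeans(mat)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1; ms_err <- ss_err / df2
  f <- if (ms_err == 0) { if (ms_cond == 0) 0 else Inf } else ms_cond / ms_err
  if (gg_correction) {
    S <- stats::cov(mat)
    eps <- gg_epsilon(S)
    p_f <- if (!is.finite(f)) 0 else if (f == 0) 1 else
      stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  } else {
    p_f <- if (!is.finite(f)) 0 else if (f == 0) 1 else
      stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  m <- k - 1
  others <- setdiff(seq_len(k), baseline_bin)
  se <- sqrt(2 * ms_err / n)
  comp <- do.call(rbind, lapply(others, function(j) {
    tj <- if (se == 0) 0 else (col_m[j] - col_m[baseline_bin]) / se
    p_raw <- if (se == 0) 1 else 2 * stats::pt(-abs(tj), df2)
    p_adj <- if (se == 0) 1 else 1 - pdunnett(abs(tj), m, df2)
    data.frame(bin = j, t = tj, p_raw = p_raw, p_adj = min(1, max(p_adj, p_raw)))
  }))
  list(anova = test_result("rm_anova", f, c(df1, df2), p_f,
                           method = if (gg_correction) "greenhouse-geisser" else "none"),
       comparisons = comp)
}

# Greenhouse-Geisser epsilon: (tr V)^2 / ((k-1) tr(V^2)), V the
# double-centred covariance
gg_epsilon <- function(S) {
  k <- ncol(S)
  Cm <- diag(k) - 1 / k
  V <- Cm %*% S %*% Cm
  (sum(diag(V))^2) / ((k - 1) * sum(V * V))
}

#' Two-way fixed-effects ANOVA with Sidak-corrected comparisons
#'
#' Full two-way ANOVA with interaction on a balanced or unbalanced design
#' (type-I sums of squares via `stats::lm`/`stats::anova`). The declared cell
#' comparisons are carried out only when the relevant main or interaction
#' effect is significant at `alpha`, with Sidak adjustment over the declared
#' family (`p_adj = 1 - (1 - p)^m`).
#'
#' @param data Data frame with columns `f1`, `f2` (factors) and `y`.
#' @param comparisons List of comparisons, each
#'   `list(within = c(f2 = <level>), levels = c(<f1 level>, <f1 level>))`.
#' @param alpha Gate for running the post hoc family.
#' @return List: `anova` (data frame of effects) and `posthoc` (data frame or
#'   NULL when the gate is closed).
#' @export
two_way_anova_sidak <- function(data, comparisons = list(), alpha = 0.05) {
  stopifnot(all(c("f1", "f2", "y") %in% names(data)))
  data$f1 <- factor(data$f1); data$f2 <- factor(data$f2)
  fit <- stats::lm(y ~ f1 * f2, data = data)
  a <- stats::anova(fit)
  tab <- data.frame(effect = rownames(a), df = a$Df, F = a$`F value`,
                    p = a$`Pr(>F)`)
  gate <- any(tab$p[tab$effect %in% c("f1", "f2", "f1:f2")] < alpha, na.rm = TRUE)
  posthoc <- NULL
  if (gate && length(comparisons)) {
    mse <- a["Residuals", "Mean Sq"]; dfe <- a["Residuals", "Df"]
    mfam <- length(comparisons)
    posthoc <- do.call(rbind, lapply(comparisons, function(cmp) {
      sel1 <- data$f1 == cmp$levels[1] & data$f2 == cmp$within
      sel2 <- data$f1 == cmp$levels[2] & data$f2 == cmp$within
      n1 <- sum(sel1); n2 <- sum(sel2)
      d <- mean(data$y[sel1]) - mean(data$y[sel2])
      t <- d / sqrt(mse * (1 / n1 + 1 / n2))
      p <- 2 * stats::pt(-abs(t), dfe)
      data.frame(within = cmp$within,
                 contrast = paste(cmp$levels, collapse = " vs "),
                 diff = d, t = t, df = dfe, p_raw = p,
                 p_sidak = 1 - (1 - p)^mfam, m = mfam)
    }))
  }
  list(anova = tab, posthoc = posthoc, gate_open = gate)
}

#' Pearson chi-square contingency test
#'
#' Without continuity correction; optional pairwise mode tests every pair of
#' columns (e.g. time periods) in addition to the omnibus table.
#'
#' @param tab Contingency table (matrix of counts).
#' @param pairwise Also test all column pairs.
#' @return A test result; with `pairwise`, a list `omnibus` + `pairwise`
#'   (named list of test results per column pair).
#' @export
chi_square_contingency <- function(tab, pairwise = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), nrow(tab) >= 2, ncol(tab) >= 2)
  one <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    stat <- sum((m - e)^2 / e)
    df <- (nrow(m) - 1) * (ncol(m) - 1)
    test_result("chi_square", stat, df,
                stats::pchisq(stat, df, lower.tail = FALSE))
  }
  if (!pairwise) return(one(tab))
  pairs <- utils::combn(ncol(tab), 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) one(tab[, pr]))
  names(pw) <- vapply(pairs, function(pr)
    paste(colnames(tab)[pr] %||% pr, collapse = " vs "), character(1))
  list(omnibus = one(tab), pairwise = pw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROUT outlier detection (one-sample case)
#'
#' Robust fit (median) with the robust standard deviation of the residuals
#' (RSDR: the 68.27th percentile of the absolute residuals scaled by
#' N/(N - K), K = 1), followed by an FDR-controlled scan of the residual
#' tails at rate Q: residuals are tested from the largest down, the i-th
#' against the threshold `alpha_i = Q (N - (i - 1)) / N` on a t distribution
#' with N - K degrees of freedom, stopping at the first non-significant one.
#'
#' @param values Numeric sample (n >= 5).
#' @param Q FDR rate (0.005 = 0.5%).
#' @return Logical outlier mask.
#' @export
rout_outliers <- function(values, Q = 0.005) {
  n <- length(values)
  if (n < 5) pe_stop("badarg", "ROUT requires at least 5 values")
  res <- values - stats::median(values)
  rsdr <- stats::quantile(abs(res), 0.6827, names = FALSE) * n / (n - 1)
  if (rsdr == 0) return(abs(res) > 0)
  tv <- abs(res) / rsdr
  ord <- order(tv, decreasing = TRUE)
  p <- 2 * stats::pt(-tv, n - 1)
  out <- logical(n)
  for (i in seq_len(n)) {
    alpha_i <- Q * (n - (i - 1)) / n
    if (p[ord[i]] < alpha_i) out[ord[i]] <- TRUE else break
  }
  out
}
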