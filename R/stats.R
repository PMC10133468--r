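# Exact two-sided Wilcoxon signed-rank p-value by dynamic programming over
# the 2^n equiprobable sign assignments. Zero differences must already be
# dropped. Ties in |d| get average ranks; doubling the ranks makes all rank
# weights integral, so the null distribution of 2*T+ is obtained by
# polynomial convolution and the two-sided p-value sums both symmetric tails
# (the distribution of T+ is symmetric about sum(ranks)/2 even under ties).
# Identical to full enumeration, but O(n^3) instead of O(2^n).
signed_rank_exact_p <- function(d) {
  n <- length(d)
  r2 <- as.integer(round(2 * rank(abs(d)))) # doubled average ranks
  W <- sum(r2)
  counts <- numeric(W + 1L)
  counts[1L] <- 1
  for (w in r2) {
    shifted <- c(numeric(w), counts[seq_len(W + 1L - w)])
    counts <- counts + shifted
  }
  t_obs <- sum(r2[d > 0])
  dev <- abs(seq(0L, W) - W / 2)
  p <- sum(counts[dev >= abs(t_obs - W / 2) - 1e-9]) / 2^n
  min(p, 1)
}

# Normal approximation with tie correction, used above `exact_max_n`.
signed_rank_normal_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (t_obs - mu) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Paired nonparametric comparison of two fittings
#'
#' Wilcoxon signed-rank test on paired per-subject values (exact null
#' distribution for up to `exact_max_n` nonzero differences, normal
#' approximation with tie correction above that), two-sided, with zero
#' differences dropped before ranking. Descriptives are medians and
#' interquartile ranges per arm, the difference of medians (control minus
#' test), and percentile-bootstrap 95% confidence intervals of each median and
#' of the median difference (subjects resampled jointly).
#'
#' @param values_test,values_control Equal-length paired per-subject vectors.
#' @param n_boot Bootstrap resamples for the confidence intervals (default
#'   10000; 0 skips the bootstrap and returns `NA` intervals).
#' @param seed Optional integer seed for the bootstrap.
#' @param exact_max_n Largest number of nonzero differences for which the
#'   exact distribution is used (default 25).
#' @param conf_level Bootstrap confidence level.
#' @return An object of class `paired_comparison`.
#' @examples
#' paired_compare(c(3, 5, 8, 10, 12), c(2, 3, 5, 6, 7), n_boot = 200, seed = 1)
#' @export
paired_compare <- function(values_test, values_control, n_boot = 10000,
                           seed = NULL, exact_max_n = 25, conf_level = 0.95) {
  stopifnot(length(values_test) == length(values_control))
  keep <- !is.na(values_test) & !is.na(values_control)
  x <- as.numeric(values_test)[keep]
  y <- as.numeric(values_control)[keep]
  d <- x - y
  dn <- d[d != 0]
  if (!length(dn)) {
    warning("all paired differences are zero; p-value set to 1")
    p <- 1
  } else if (length(dn) <= exact_max_n) {
    p <- signed_rank_exact_p(dn)
  } else {
    p <- signed_rank_normal_p(dn)
  }

  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci_t <- ci_c <- ci_d <- c(NA_real_, NA_real_)
  if (n_boot > 0 && length(x) > 1L) {
    boot <- with_seed(seed, {
      idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                    nrow = n_boot)
      mt <- apply(idx, 1L, function(i) stats::median(x[i]))
      mc <- apply(idx, 1L, function(i) stats::median(y[i]))
      list(mt = mt, mc = mc)
    })
    ci_t <- unname(stats::quantile(boot$mt, qs))
    ci_c <- unname(stats::quantile(boot$mc, qs))
    ci_d <- unname(stats::quantile(boot$mc - boot$mt, qs))
  }

  structure(list(
    n = length(x), n_nonzero = length(dn),
    median_test = stats::median(x), median_control = stats::median(y),
    iqr_test = stats::IQR(x), iqr_control = stats::IQR(y),
    median_difference = stats::median(y) - stats::median(x),
    p_value = p,
    ci95_test = ci_t, ci95_control = ci_c, ci95_difference = ci_d,
    conf_level = conf_level, n_boot = n_boot),
    class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison (Wilcoxon signed-rank, n = %d, %d nonzero differences)\n",
              x$n, x$n_nonzero))
  cat(sprintf("  control: median %.3g (IQR %.3g);  test: median %.3g (IQR %.3g)\n",
              x$median_control, x$iqr_control, x$median_test, x$iqr_test))
  cat(sprintf("  difference of medians (control - test): %.3g", x$median_difference))
  if (!any(is.na(x$ci95_difference))) {
    cat(sprintf("  [%.3g, %.3g] (%.0f%% bootstrap CI)",
                x$ci95_difference[1L], x$ci95_difference[2L],
                100 * x$conf_level))
  }
  cat(sprintf("\n  two-sided p = %.4g\n", x$p_value))
  invisible(x)
}

#' Holm-Bonferroni step-down correction
#'
#' Adjusts a family of p-values with the Holm step-down procedure and reports
#' reject/retain decisions at `alpha`. Adjusted p-values are monotone
#' non-decreasing in rank, at least as large as the raw values and never
#' larger than plain Bonferroni.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data frame with `p`, `p_adjusted`, `reject`.
#' @examples
#' holm_bonferroni(c(0.01, 0.04))
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p, method = "holm")
  data.frame(p = p, p_adjusted = adj, reject = adj <= alpha)
}
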