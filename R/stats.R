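# Group statistics: assumption-gated two-sample comparison (Student's t vs.
# Mann-Whitney U), Pearson correlation, Bonferroni correction, effect sizes.

#' Assumption-gated two-group comparison
#'
#' Tests normality of both groups (Shapiro-Wilk) and homogeneity of variance
#' (Levene's test, mean-centered); when both groups pass Shapiro-Wilk and
#' Levene passes, a Student's t-test (pooled variance) is used, otherwise a
#' Mann-Whitney U test. Degenerate (zero-variance) samples fall through to
#' the Mann-Whitney branch with a warning. Cohen's d (pooled SD) accompanies
#' the t-test; the rank-biserial correlation `1 - 2U/(n1*n2)` accompanies
#' the U test.
#'
#' @param a,b numeric samples (n >= 3 each).
#' @param alpha significance level, also used for the assumption gates.
#' @param variable optional variable name carried into the result.
#' @return object of class `group_comparison`: list with `variable`,
#'   `test_used`, `statistic`, `p`, `effect_size`, `effect_type`,
#'   `gates` (named logical), and per-group `summary` (n, mean, sd).
#' @export
compare_groups <- function(a, b, alpha = 0.05, variable = NA_character_) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L) {
    stop_nav("need at least 3 observations per group")
  }
  degenerate <- stats::sd(a) == 0 || stats::sd(b) == 0
  if (degenerate) {
    warning("zero-variance sample; falling back to Mann-Whitney U test")
  }
  gates <- c(shapiro_a = NA, shapiro_b = NA, levene = NA)
  if (!degenerate) {
    gates["shapiro_a"] <- stats::shapiro.test(a)$p.value > alpha
    gates["shapiro_b"] <- stats::shapiro.test(b)$p.value > alpha
    y <- c(a, b)
    g <- factor(rep(c("a", "b"), c(length(a), length(b))))
    lev <- car::leveneTest(y, g, center = mean)
    gates["levene"] <- lev[["Pr(>F)"]][1] > alpha
  }
  use_t <- !degenerate && all(gates)
  n1 <- length(a); n2 <- length(b)
  if (use_t) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
                 (n1 + n2 - 2))
    res <- list(test_used = "student_t",
                statistic = unname(tt$statistic), p = tt$p.value,
                effect_size = (mean(a) - mean(b)) / sp, effect_type = "cohen_d")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    U <- unname(wt$statistic)
    res <- list(test_used = "mann_whitney",
                statistic = U, p = wt$p.value,
                effect_size = 1 - 2 * U / (n1 * n2),
                effect_type = "rank_biserial")
  }
  structure(c(list(variable = variable), res,
              list(gates = gates,
                   summary = data.frame(group = c("a", "b"), n = c(n1, n2),
                                        mean = c(mean(a), mean(b)),
                                        sd = c(stats::sd(a), stats::sd(b))))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$variable, ": ", x$test_used, " statistic=",
      signif(x$statistic, 4), ", p=", signif(x$p, 3), ", ", x$effect_type,
      "=", signif(x$effect_size, 3), "\n", sep = "")
  invisible(x)
}

#' Correlation between two paired variables
#'
#' Pearson (default) or Spearman correlation with a two-sided p-value, plus
#' the Bonferroni-corrected alpha for the declared family of tests.
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped,
#'   n >= 4).
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha nominal significance level.
#' @param family_size number of correlations in the family (Bonferroni).
#' @param pair optional name of the variable pair.
#' @return object of class `correlation_result`: list with `pair`, `r`, `p`,
#'   `n`, `alpha_corrected`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"), alpha = 0.05,
                      family_size = 1L, pair = NA_character_) {
  method <- match.arg(method)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop_nav("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(structure(list(pair = pair, r = NA_real_, p = NA_real_,
                          n = length(x),
                          alpha_corrected = bonferroni(alpha, family_size),
                          method = method),
                     class = "correlation_result"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  structure(list(pair = pair, r = unname(ct$estimate), p = ct$p.value,
                 n = length(x),
                 alpha_corrected = bonferroni(alpha, family_size),
                 method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> ", x$pair, ": r=", signif(x$r, 3), ", p=",
      signif(x$p, 3), ", n=", x$n, " (alpha_corrected=",
      signif(x$alpha_corrected, 3), ")\n", sep = "")
  invisible(x)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha nominal level.
#' @param m family size (number of tests).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop_nav("family size must be >= 1")
  }
  alpha / m
}
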