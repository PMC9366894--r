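#' D'Agostino-Pearson omnibus K2 normality test
#'
#' Own implementation of the omnibus test combining the small-sample
#' Z-transforms of sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983): \eqn{K^2 = Z_{g1}^2 + Z_{g2}^2}, referred to a
#' chi-square distribution with 2 degrees of freedom. Requires n >= 8,
#' below which the kurtosis transform is undefined.
#'
#' @param x numeric sample.
#' @return list with `k2`, `p_value`, `z_skew`, `z_kurt`, `n`.
#' @examples
#' dagostino_pearson_k2(rnorm(50))
#' @export
dagostino_pearson_k2 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson K2 requires n >= 8")
  if (stats::sd(x) == 0) stop("constant sample")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(k2 = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Compare groups with normality-gated test selection
#'
#' Implements the decision logic used throughout the analyses: in `auto`
#' mode, every group is tested for normality with the D'Agostino-Pearson
#' K2 test at alpha = 0.05; if all groups pass, a parametric test is used
#' (two-sided t-test for 2 groups, one-way ANOVA for more), otherwise a
#' rank test (Mann-Whitney U for 2 groups, Kruskal-Wallis for more). The
#' decision trace records every verdict. Groups too small for K2 (n < 8)
#' route to the nonparametric branch with a note.
#'
#' @param groups named list of numeric vectors, each of length >= 3.
#' @param mode `"auto"`, `"parametric"` or `"nonparametric"`.
#' @param paired use paired tests (2 groups only).
#' @param alpha normality alpha for the gate (default 0.05).
#' @return list of class `group_test` with `test`, `statistic`, `p_value`,
#'   `n`, `normality` (per-group p values or `NA`), and
#'   `decision_trace` (character).
#' @export
compare_groups <- function(groups, mode = c("auto", "parametric", "nonparametric"),
                           paired = FALSE, alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, 0L) < 3L)) stop("each group needs n >= 3")
  k <- length(groups)
  trace <- sprintf("mode=%s, %d groups (n = %s)", mode, k,
                   paste(vapply(groups, length, 0L), collapse = ", "))

  norm_p <- rep(NA_real_, k)
  if (mode == "auto") {
    for (i in seq_len(k)) {
      norm_p[i] <- tryCatch(dagostino_pearson_k2(groups[[i]])$p_value,
                            error = function(e) NA_real_)
      trace <- c(trace, sprintf("K2 normality %s: p = %s -> %s", names(groups)[i],
                                format(norm_p[i], digits = 3),
                                if (is.na(norm_p[i])) "not testable (n < 8)"
                                else if (norm_p[i] > alpha) "pass" else "fail"))
    }
    parametric <- all(!is.na(norm_p)) && all(norm_p > alpha)
    trace <- c(trace, sprintf("all groups normal: %s -> %s path", parametric,
                              if (parametric) "parametric" else "nonparametric"))
  } else {
    parametric <- mode == "parametric"
    trace <- c(trace, sprintf("forced %s path", mode))
  }

  if (k == 2L) {
    if (parametric) {
      ht <- stats::t.test(groups[[1L]], groups[[2L]], paired = paired,
                          var.equal = TRUE)
      test <- if (paired) "paired t-test" else "t-test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(groups[[1L]], groups[[2L]],
                                                paired = paired))
      test <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U"
    }
  } else {
    if (paired) stop("paired comparison supports exactly 2 groups")
    vals <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), vapply(groups, length, 0L)))
    if (parametric) {
      ht <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
      test <- "one-way ANOVA"
    } else {
      ht <- stats::kruskal.test(vals, fac)
      test <- "Kruskal-Wallis"
    }
  }
  trace <- c(trace, sprintf("selected: %s", test))
  structure(list(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value, n = vapply(groups, length, 0L),
                 normality = stats::setNames(norm_p, names(groups)),
                 decision_trace = trace),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic, x$p_value))
  cat(paste0("  ", x$decision_trace, collapse = "\n"), "\n")
  invisible(x)
}

#' Power of a one-way ANOVA for a Cohen's f effect size
#'
#' @param n per-group sample size.
#' @param f Cohen's f effect size.
#' @param groups number of groups (>= 2).
#' @param alpha significance level.
#' @return power in `[0, 1]`, from the noncentral F distribution with
#'   noncentrality `f^2 * groups * n`.
#' @export
anova_power <- function(n, f, groups = 2L, alpha = 0.05) {
  stopifnot(n >= 2, f > 0, groups >= 2L, alpha > 0, alpha < 1)
  df1 <- groups - 1L
  df2 <- groups * (n - 1L)
  ncp <- f^2 * groups * n
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = ncp, lower.tail = FALSE)
}

#' Smallest per-group sample size reaching a target power
#'
#' One-way ANOVA power analysis for a Cohen's f effect size (for two
#' groups this coincides with the two-sided two-sample t-test with
#' d = 2f). Returns the smallest integer n per group whose power meets the
#' target.
#'
#' @param f Cohen's f effect size (0.25 = "medium").
#' @param power target power (default 0.90).
#' @param groups number of groups.
#' @param alpha significance level (default 0.05).
#' @param n_max search bound; an unreachable target raises an error.
#' @return list with `n_per_group` and the achieved `power`.
#' @examples
#' sample_size_anova(f = 0.25, power = 0.90, groups = 2)
#' @export
sample_size_anova <- function(f, power = 0.90, groups = 2L, alpha = 0.05,
                              n_max = 1e5L) {
  stopifnot(f > 0, power > 0, power < 1)
  for (n in 2:n_max) {
    p <- anova_power(n, f, groups, alpha)
    if (p >= power) return(list(n_per_group = n, power = p))
  }
  stop(sprintf("target power %.2f not reachable with n <= %d", power, n_max))
}

#' Coefficient of variation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation, reported in
#' percent. Used to compare the spread of recovery half-times between
#' conditions.
#'
#' @param x numeric sample with positive mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 40.82
#' @export
coefficient_of_variation <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  if (!is.finite(m) || m <= 0) stop("coefficient of variation requires a positive mean")
  100 * stats::sd(x) / m
}
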