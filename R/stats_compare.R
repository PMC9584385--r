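#' Normality-routed comparison of a continuous variable between two groups
#'
#' Applies a Shapiro-Wilk test to each group at \code{alpha_normality};
#' when both groups are compatible with normality the two-sided Welch
#' (unequal-variance) t-test is used, otherwise the two-sided Mann-Whitney
#' U test. The Mann-Whitney test is exact when the smaller group has at
#' most 20 observations and there are no ties, and uses the tie-corrected
#' normal approximation otherwise.
#'
#' @param x0,x1 numeric vectors for the two groups (each n >= 3).
#' @param alpha_normality per-group Shapiro-Wilk significance level.
#' @param variable optional variable name carried into the result.
#' @param test \code{"auto"} (default) applies the normality routing;
#'   \code{"t-test"} or \code{"mann-whitney"} forces a route.
#' @return A list of class \code{vf_test}: \code{variable},
#'   \code{test_used} (\code{"t-test"} or \code{"mann-whitney"}),
#'   \code{statistic}, \code{p_value}, \code{normality_p} (per-group
#'   Shapiro-Wilk p-values), \code{group_summary}.
#' @export
compare_continuous <- function(x0, x1, alpha_normality = 0.05, variable = "x",
                               test = c("auto", "t-test", "mann-whitney")) {
  test <- match.arg(test)
  x0 <- x0[is.finite(x0)]; x1 <- x1[is.finite(x1)]
  if (length(x0) < 3L || length(x1) < 3L)
    stop("each group needs at least 3 finite observations", call. = FALSE)
  if (sd(x0) == 0 && sd(x1) == 0)
    stop(sprintf("'%s' is constant in both groups; comparison is degenerate", variable),
         call. = FALSE)
  sw <- function(x) if (sd(x) == 0) 0 else shapiro.test(x)$p.value
  np <- c(group0 = sw(x0), group1 = sw(x1))
  route_t <- if (test == "auto") all(np >= alpha_normality) else test == "t-test"
  if (route_t) {
    ht <- t.test(x0, x1, var.equal = FALSE)
    used <- "t-test"
  } else {
    ties <- anyDuplicated(c(x0, x1)) > 0L
    exact <- min(length(x0), length(x1)) <= 20L && !ties
    ht <- suppressWarnings(wilcox.test(x0, x1, exact = exact, correct = TRUE))
    used <- "mann-whitney"
  }
  structure(list(variable = variable, test_used = used,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 normality_p = np,
                 group_summary = rbind(group0 = c(n = length(x0), mean = mean(x0), sd = sd(x0)),
                                       group1 = c(n = length(x1), mean = mean(x1), sd = sd(x1)))),
            class = "vf_test")
}

#' Comparison of a categorical variable between two groups
#'
#' Fisher's exact test (two-sided) when any expected cell count is below 5,
#' otherwise the chi-square test with continuity correction.
#'
#' @param tab a 2x2 matrix of non-negative integer counts with both row and
#'   column margins positive.
#' @param variable optional variable name carried into the result.
#' @return A list of class \code{vf_test} with \code{test_used}
#'   (\code{"fisher"} or \code{"chi-square"}), \code{statistic} (chi-square
#'   statistic or odds ratio for Fisher), \code{p_value},
#'   \code{expected_counts}.
#' @export
compare_categorical <- function(tab, variable = "x") {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab)))
    stop("`tab` must be a 2x2 matrix of non-negative integer counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop(sprintf("'%s' has a zero margin; comparison is degenerate", variable),
         call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ht <- fisher.test(tab)
    used <- "fisher"
    stat <- unname(ht$estimate)
  } else {
    ht <- chisq.test(tab, correct = TRUE)
    used <- "chi-square"
    stat <- unname(ht$statistic)
  }
  structure(list(variable = variable, test_used = used, statistic = stat,
                 p_value = ht$p.value, expected_counts = expected),
            class = "vf_test")
}

#' @export
print.vf_test <- function(x, ...) {
  cat(sprintf("<%s> %s: statistic %.4g, p = %.4g\n", x$test_used, x$variable,
              x$statistic, x$p_value))
  invisible(x)
}

#' Cohen's kappa for two categorical raters
#'
#' Chance-corrected agreement \code{kappa = (p_o - p_e) / (1 - p_e)} with
#' chance agreement from the product of the marginal rating distributions.
#' The confidence interval uses the large-sample standard error
#' \code{sqrt(p_o (1 - p_o)) / ((1 - p_e) sqrt(n))}, truncated to [-1, 1].
#'
#' @param ratings_a,ratings_b equal-length categorical vectors (length >= 2)
#'   over the same category set.
#' @param conf_level confidence level for the interval.
#' @return A list of class \code{vf_agreement} with \code{measure = "kappa"},
#'   \code{value}, \code{ci}, \code{p_observed}, \code{p_expected}, \code{n}.
#' @export
cohen_kappa <- function(ratings_a, ratings_b, conf_level = 0.95) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 2L)
    stop("ratings must have equal length >= 2", call. = FALSE)
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = lev)
  b <- factor(as.character(ratings_b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < 1e-12)
    stop("kappa undefined: both raters are constant (chance agreement = 1)",
         call. = FALSE)
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / n) / (1 - p_e)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(kappa + c(-1, 1) * z * se, -1), 1)
  structure(list(measure = "kappa", value = kappa, ci = ci,
                 p_observed = p_o, p_expected = p_e, n = n),
            class = "vf_agreement")
}

#' Two-way intraclass correlation for two raters, ICC(2,1)
#'
#' Single-measure, absolute-agreement intraclass correlation under the
#' two-way random-effects model, computed from the two-way ANOVA
#' decomposition:
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' with MSR, MSC and MSE the subject, rater and error mean squares.
#' Absolute agreement penalises systematic rater shifts, unlike the
#' consistency variant. The confidence interval follows the F-based
#' formulas of McGraw and Wong with Satterthwaite degrees of freedom.
#'
#' @param ratings numeric matrix, subjects in rows (>= 5) and exactly 2
#'   rater columns, no missing cells.
#' @param conf_level confidence level for the interval.
#' @return A list of class \code{vf_agreement} with \code{measure = "icc"},
#'   \code{value}, \code{ci}, and the mean squares.
#' @export
icc_two_way <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 2L) stop("expected exactly 2 rater columns", call. = FALSE)
  if (nrow(ratings) < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (any(!is.finite(ratings))) stop("missing or non-finite cells", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  if (msr < 1e-12)
    stop("icc undefined: no between-subject variance", call. = FALSE)
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  if (mse < 1e-12 && msc < 1e-12) {
    ci <- c(1, 1)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- pmin(pmax(c(lower, upper), -1), 1)
  }
  structure(list(measure = "icc", value = icc, ci = ci,
                 ms = c(msr = msr, msc = msc, mse = mse), n = n, k = k),
            class = "vf_agreement")
}

#' @export
print.vf_agreement <- function(x, ...) {
  cat(sprintf("<%s> %.4f (95%% CI %.4f-%.4f), n = %d\n", x$measure, x$value,
              x$ci[1], x$ci[2], x$n))
  invisible(x)
}
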