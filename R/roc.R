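#' ROC analysis with bootstrap confidence interval and Youden operating point
#'
#' The AUC is computed by the rank (trapezoidal) method with midrank tie
#' handling, which makes it identical to the normalised Mann-Whitney U
#' statistic \code{U / (n1 n0)}. The confidence interval is a class-
#' stratified percentile bootstrap. The reported operating point maximises
#' Youden's J (sensitivity + specificity - 1) over thresholds of the form
#' "positive if score >= t"; among ties the lowest threshold (highest
#' sensitivity) is taken.
#'
#' @param scores numeric predictor or model score, higher = more positive.
#' @param labels binary labels (0/1, logical, or two-level factor with the
#'   second sorted level treated as positive).
#' @param n_boot number of bootstrap replicates for the CI.
#' @param seed integer seed for the bootstrap (global RNG untouched).
#' @param conf_level confidence level.
#' @return A list of class \code{vf_roc}: \code{auc}, \code{auc_ci},
#'   \code{threshold}, \code{sensitivity}, \code{specificity},
#'   \code{accuracy}, \code{youden_j}, \code{curve} (data frame of
#'   threshold, sensitivity, specificity), \code{n_pos}, \code{n_neg}.
#' @export
roc_analysis <- function(scores, labels, n_boot = 2000, seed = 1,
                         conf_level = 0.95) {
  y <- as_binary_labels(labels)
  s <- as.numeric(scores)
  if (length(s) != length(y)) stop("scores and labels differ in length", call. = FALSE)
  ok <- is.finite(s) & !is.na(y)
  s <- s[ok]; y <- y[ok]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present for ROC analysis", call. = FALSE)
  auc <- auc_rank(s, y)
  # sweep thresholds "positive if score >= t" via cumulative counts over the
  # score-sorted sample; one entry per distinct score value
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]; ss <- s[ord]
  ends <- c(which(diff(ss) != 0), length(ss))   # last index of each tie block
  sens <- cumsum(ys)[ends] / n1
  spec <- 1 - cumsum(1 - ys)[ends] / n0
  thr <- ss[ends]
  # ascending threshold order (highest sensitivity first among J ties)
  o <- rev(seq_along(thr))
  thr <- thr[o]; sens <- sens[o]; spec <- spec[o]
  j <- sens + spec - 1
  best <- which(j == max(j))[1]
  threshold <- thr[best]
  acc <- mean((s >= threshold) == (y == 1L))
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci <- withr::with_seed(as.integer(seed), {
      idx1 <- which(y == 1L); idx0 <- which(y == 0L)
      reps <- vapply(seq_len(n_boot), function(i) {
        b <- c(sample(idx1, n1, replace = TRUE), sample(idx0, n0, replace = TRUE))
        auc_rank(s[b], y[b])
      }, numeric(1))
      unname(quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)))
    })
  }
  structure(list(auc = auc, auc_ci = ci, threshold = threshold,
                 sensitivity = sens[best], specificity = spec[best],
                 accuracy = acc, youden_j = j[best],
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 n_pos = n1, n_neg = n0, n_boot = n_boot, seed = seed),
            class = "vf_roc")
}

# AUC via midranks: (sum of positive ranks - n1(n1+1)/2) / (n1 n0),
# identical to the Mann-Whitney U statistic divided by n1*n0
auc_rank <- function(s, y) {
  r <- rank(s)
  n1 <- as.numeric(sum(y == 1L)); n0 <- as.numeric(sum(y == 0L))
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels) || is.character(labels)) {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) != 2L) stop("labels must have exactly 2 levels", call. = FALSE)
    return(as.integer(as.character(labels) == lev[2]))
  }
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1", call. = FALSE)
  y
}

#' @export
print.vf_roc <- function(x, ...) {
  cat(sprintf("<roc> AUC %.3f (95%% CI %.3f-%.3f), n = %d/%d pos/neg\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  cat(sprintf("  Youden threshold %.4g: sens %.3f, spec %.3f, acc %.3f\n",
              x$threshold, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x a \code{vf_roc} object.
#' @param ... passed to \code{plot}.
#' @export
plot.vf_roc <- function(x, ...) {
  fpr <- c(1, rev(1 - x$curve$specificity), 0)
  tpr <- c(1, rev(x$curve$sensitivity), 0)
  graphics::plot(fpr, tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  best <- which(x$curve$threshold == x$threshold)
  graphics::points(1 - x$curve$specificity[best], x$curve$sensitivity[best],
                   pch = 19)
  invisible(x)
}
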