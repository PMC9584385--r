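#' Maximum-likelihood logistic regression with separation diagnostics
#'
#' Fits a binomial logistic model by iteratively reweighted least squares
#' and reports odds ratios with Wald confidence intervals. Before fitting,
#' each term is screened for complete or quasi-complete separation
#' (disjoint or boundary-touching predictor ranges across outcome classes);
#' separated terms are flagged and their odds ratios and confidence limits
#' reported as \code{NA} rather than as the spuriously large estimates a
#' diverging likelihood would produce. The model as a whole is additionally
#' flagged when the fit perfectly classifies the outcome.
#'
#' @param data data frame containing the outcome and terms.
#' @param outcome name of a binary (0/1 or two-level) outcome column with
#'   both classes present.
#' @param terms character vector of predictor column names.
#' @return A list of class \code{vf_logistic}: \code{terms},
#'   \code{coefficients}, \code{table} (data frame with term, estimate, SE,
#'   OR, CI, p-value, separation flag), \code{log_likelihood},
#'   \code{separation} (named logical per term), \code{model_separated},
#'   \code{converged}, \code{fit} (the underlying \code{glm} object),
#'   \code{n}, \code{outcome}.
#' @export
fit_logistic <- function(data, outcome, terms) {
  y <- binary_outcome(data, outcome)
  if (length(terms) < 1L) stop("need at least one model term", call. = FALSE)
  missing_cols <- setdiff(terms, names(data))
  if (length(missing_cols))
    stop("terms not in data: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(data) <= length(terms) + 1L)
    stop("need n > number of terms + 1", call. = FALSE)
  sep <- vapply(terms, function(v) term_separation(as.numeric(data[[v]]), y),
                character(1))
  separated <- sep != "none"
  df <- data.frame(.y = y, data[terms], check.names = FALSE)
  fml <- as.formula(paste(".y ~", paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = df,
                              control = list(maxit = 100)))
  sm <- suppressWarnings(summary(fit))$coefficients
  rn <- gsub("`", "", rownames(sm))
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]; pv <- sm[, "Pr(>|z|)"]
  z <- qnorm(0.975)
  tab <- data.frame(term = rn, estimate = est, se = se,
                    or = exp(est), or_low = exp(est - z * se),
                    or_high = exp(est + z * se), p_value = pv,
                    separated = c(FALSE, separated)[match(rn, c("(Intercept)", terms))],
                    row.names = NULL, stringsAsFactors = FALSE)
  tab[tab$separated %in% TRUE, c("or", "or_low", "or_high", "p_value")] <- NA_real_
  probs <- fitted(fit)
  model_separated <- any(separated) ||
    (all(probs[y == 1] > 1 - 1e-6) && all(probs[y == 0] < 1e-6))
  structure(list(terms = terms, coefficients = setNames(est, rn), table = tab,
                 log_likelihood = as.numeric(logLik(fit)),
                 separation = setNames(separated, terms),
                 separation_kind = setNames(sep, terms),
                 model_separated = model_separated,
                 converged = fit$converged, fit = fit,
                 n = nrow(data), outcome = outcome),
            class = "vf_logistic")
}

#' @export
print.vf_logistic <- function(x, ...) {
  cat(sprintf("<logistic model> %s ~ %s  (n = %d, logLik %.2f%s)\n",
              x$outcome, paste(x$terms, collapse = " + "), x$n,
              x$log_likelihood,
              if (x$model_separated) ", SEPARATION" else ""))
  print(x$table, digits = 4)
  invisible(x)
}

binary_outcome <- function(data, outcome) {
  if (!outcome %in% names(data))
    stop(sprintf("outcome column '%s' not found", outcome), call. = FALSE)
  y <- data[[outcome]]
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2L)
      stop(sprintf("outcome '%s' must have exactly 2 levels", outcome), call. = FALSE)
    y <- as.integer(as.character(y) == lev[2])
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    stop(sprintf("outcome '%s' must be binary 0/1", outcome), call. = FALSE)
  if (length(unique(y)) < 2L)
    stop(sprintf("outcome '%s' has a single class", outcome), call. = FALSE)
  y
}

# one-dimensional separation check: "complete" when predictor ranges of the
# two outcome classes are disjoint, "quasi" when they touch only at the
# boundary, "none" otherwise (constant predictors are "none": no information,
# but no monotone likelihood either)
term_separation <- function(x, y) {
  x1 <- x[y == 1]; x0 <- x[y == 0]
  if (length(unique(x)) < 2L) return("none")
  if (min(x1) > max(x0) || min(x0) > max(x1)) return("complete")
  if (min(x1) >= max(x0) || min(x0) >= max(x1)) return("quasi")
  "none"
}

#' Variance inflation factors for a set of numeric columns
#'
#' Classical VIF on the design matrix: for each column, \code{1 / (1 - R^2)}
#' from the least-squares regression of that column on the others
#' (\code{Inf} for exactly collinear columns). Values of 10 or more
#' conventionally indicate problematic multicollinearity.
#'
#' @param data data frame.
#' @param terms character vector of 2 or more numeric column names.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(data, terms) {
  if (length(terms) < 2L)
    return(setNames(rep(1, length(terms)), terms))
  x <- as.matrix(data.frame(lapply(data[terms], as.numeric)))
  out <- vapply(seq_along(terms), function(j) {
    fit <- lm(x[, j] ~ x[, -j, drop = FALSE])
    ss_tot <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- if (ss_tot <= 0) 0 else 1 - sum(fit$residuals^2) / ss_tot
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(pmax(out, 1), terms)
}

#' Univariable logistic screen
#'
#' Fits a single-predictor logistic model per candidate term and reports
#' the Wald p-value, odds ratio and confidence interval of each, the
#' screening step preceding multivariable modelling. Terms exhibiting
#' complete separation are flagged and carry \code{NA} in place of an odds
#' ratio (their models "could not be performed").
#'
#' @param data data frame.
#' @param outcome binary outcome column name.
#' @param terms candidate predictor names.
#' @return Data frame with one row per term: estimate, OR and CI, p-value,
#'   separation flag.
#' @export
univariable_screen <- function(data, outcome, terms) {
  rows <- lapply(terms, function(v) {
    m <- fit_logistic(data, outcome, v)
    r <- m$table[m$table$term == v, , drop = FALSE]
    r
  })
  do.call(rbind, rows)
}

#' Backward likelihood-ratio elimination for logistic models
#'
#' Implements the published model-building procedure: candidate terms are
#' those passing the univariable screen at \code{p_enter}; the multivariable
#' model then iteratively drops the term with the largest likelihood-ratio
#' test p-value until every remaining term has LR p below \code{p_stay}.
#' Variance inflation factors are computed on the candidate design matrix
#' and terms at VIF >= 10 are reported (not removed automatically). The
#' full elimination trace is retained: every removed term had LR p >=
#' \code{p_stay} at its removal step.
#'
#' @param data data frame.
#' @param outcome binary outcome column name.
#' @param candidate_terms non-empty character vector of candidate
#'   predictors.
#' @param p_enter univariable screening threshold.
#' @param p_stay multivariable retention threshold (likelihood-ratio test).
#' @return A list of class \code{vf_selection}: \code{univariable} (screen
#'   table), \code{candidates}, \code{vif}, \code{high_vif_terms},
#'   \code{elimination_trace} (data frame of removed terms with LR
#'   p-values), \code{final} (a \code{\link{fit_logistic}} model, or
#'   \code{NULL} when no candidate survives), \code{final_terms}.
#' @export
backward_eliminate <- function(data, outcome, candidate_terms,
                               p_enter = 0.05, p_stay = 0.05) {
  if (!length(candidate_terms)) stop("`candidate_terms` is empty", call. = FALSE)
  uni <- univariable_screen(data, outcome, candidate_terms)
  keep <- uni$term[!is.na(uni$p_value) & uni$p_value < p_enter & !uni$separated]
  vifs <- if (length(keep) >= 2L) vif(data, keep) else
    setNames(rep(1, length(keep)), keep)
  trace <- data.frame(step = integer(0), term = character(0),
                      lr_p = numeric(0), stringsAsFactors = FALSE)
  if (!length(keep)) {
    return(structure(list(univariable = uni, candidates = character(0),
                          vif = vifs, high_vif_terms = character(0),
                          elimination_trace = trace, final = NULL,
                          final_terms = character(0),
                          p_enter = p_enter, p_stay = p_stay),
                     class = "vf_selection"))
  }
  cur <- keep
  step <- 0L
  while (length(cur)) {
    fit <- fit_logistic(data, outcome, cur)
    lrt <- drop1(fit$fit, test = "LRT")
    lr_p <- setNames(lrt[["Pr(>Chi)"]][-1], gsub("`", "", rownames(lrt)[-1]))
    lr_p[is.na(lr_p)] <- 1   # aliased term: dropping it costs no likelihood
    worst <- names(lr_p)[which.max(lr_p)]
    if (lr_p[[worst]] < p_stay) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, term = worst,
                                     lr_p = unname(lr_p[[worst]]),
                                     stringsAsFactors = FALSE))
    cur <- setdiff(cur, worst)
  }
  final <- if (length(cur)) fit_logistic(data, outcome, cur) else NULL
  structure(list(univariable = uni, candidates = keep, vif = vifs,
                 high_vif_terms = names(vifs)[vifs >= 10],
                 elimination_trace = trace, final = final, final_terms = cur,
                 p_enter = p_enter, p_stay = p_stay),
            class = "vf_selection")
}

#' @export
print.vf_selection <- function(x, ...) {
  cat(sprintf("<model selection> %d candidate(s) after univariable screen (p < %g)\n",
              length(x$candidates), x$p_enter))
  if (length(x$high_vif_terms))
    cat("  VIF >= 10:", paste(x$high_vif_terms, collapse = ", "), "\n")
  if (nrow(x$elimination_trace)) {
    cat("  eliminated:\n")
    print(x$elimination_trace)
  }
  if (is.null(x$final)) {
    cat("  final model: empty (no candidate survived)\n")
  } else {
    cat("  final terms:", paste(x$final_terms, collapse = " + "), "\n")
  }
  invisible(x)
}
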