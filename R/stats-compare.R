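#' z-transform a vector
#'
#' Centres to mean 0 and scales to sample standard deviation 1 (n-1
#' denominator), so regression slopes on different metrics are not
#' affected by their differing variances.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @param name label used in the zero-variance error message.
#' @return numeric vector with mean 0 and sd 1.
#' @export
zscore <- function(x, name = deparse(substitute(x))) {
  if (length(x) < 2L) stop("zscore needs at least 2 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance in ", name, "; cannot z-score")
  (x - mean(x)) / s
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Pearson's r with a 95% confidence interval from the Fisher
#' z-transformation (atanh(r) +/- 1.96/sqrt(n-3)) and a two-sided p-value
#' from the t distribution with n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 4, finite,
#'   non-constant.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `correlation_estimate`: list with `r`, `n`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("need n >= 4 for a Fisher-z interval")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  structure(list(r = unname(ct$estimate), n = length(x),
                 ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                 p = ct$p.value),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d, 95%% CI %.3f to %.3f, p = %.3g)\n",
              x$r, x$n, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Compare two correlation estimates
#'
#' `method = "ci_overlap"` declares the correlations different iff their
#' 95% confidence intervals are disjoint (the conservative criterion used
#' for the headline comparisons). `method = "dependent_test"` applies
#' Steiger's z-test for two dependent correlations sharing one variable
#' (r(x,y1) vs r(x,y2)); it needs the correlation `r_between` between the
#' two non-shared variables and equal sample sizes.
#'
#' @param a,b `correlation_estimate` objects.
#' @param method `"ci_overlap"` or `"dependent_test"`.
#' @param r_between correlation between the two non-shared variables
#'   (required for `dependent_test`).
#' @return list with `method`, `different` (logical), and for the
#'   dependent test `z` and `p`.
#' @export
compare_correlations <- function(a, b, method = c("ci_overlap", "dependent_test"),
                                 r_between = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(a, "correlation_estimate"),
            inherits(b, "correlation_estimate"))
  if (method == "ci_overlap") {
    different <- a$ci_high < b$ci_low || b$ci_high < a$ci_low
    return(list(method = method, different = different))
  }
  if (a$n != b$n) stop("dependent test needs both correlations on the same sample")
  if (is.null(r_between)) stop("dependent test needs r_between")
  n <- a$n
  r12 <- a$r; r13 <- b$r; r23 <- r_between
  # Steiger (1980) Z* for H0: rho12 = rho13 with common variable 1
  rbar <- (r12 + r13) / 2
  det_term <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  z12 <- atanh(r12); z13 <- atanh(r13)
  z <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * psi / (1 - rbar^2)^2))
  p <- 2 * stats::pnorm(-abs(z))
  list(method = method, different = p < 0.05, z = z, p = p,
       det_term = det_term)
}

#' Logistic regression of a binary outcome on one predictor
#'
#' Maximum-likelihood binary logistic regression with Wald 95% confidence
#' interval and p-value for the slope. The predictor is z-transformed
#' internally by default so slopes are comparable across metrics.
#' Complete or quasi-complete separation is detected and flagged rather
#' than silently returning divergent estimates.
#'
#' @param y binary (0/1 or logical) response; both classes must occur.
#' @param x numeric predictor.
#' @param standardize z-score `x` before fitting (default `TRUE`).
#' @return object of class `logistic_fit`: list with `slope`,
#'   `intercept`, `ci_low`, `ci_high`, `p`, `separation`, `n`.
#' @export
logistic_fit <- function(y, x, standardize = TRUE) {
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("response has a single class")
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (standardize) x <- zscore(x, "predictor")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- summary(fit)$coefficients
  slope <- cf["x", "Estimate"]
  se <- cf["x", "Std. Error"]
  separation <- sep_warn || abs(slope) > 15 || se > 100
  structure(list(slope = slope, intercept = cf["(Intercept)", "Estimate"],
                 ci_low = slope - stats::qnorm(0.975) * se,
                 ci_high = slope + stats::qnorm(0.975) * se,
                 p = cf["x", "Pr(>|z|)"], separation = separation,
                 n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("slope = %.3f (95%% CI %.3f to %.3f, p = %.3g)%s\n",
              x$slope, x$ci_low, x$ci_high, x$p,
              if (x$separation) " [separation detected]" else ""))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing the hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed
#' one — the dominant two-sided convention.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in 2x2 table")
  }
  stats::fisher.test(tab)$p.value
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Rank-sum W statistic with midrank ties; exact p for small samples
#' without ties (combined n <= 20), otherwise the normal approximation
#' with continuity correction.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with `W` and two-sided `p`.
#' @export
rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(W = unname(wt$statistic), p = wt$p.value)
}
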