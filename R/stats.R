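#' Normality screening of a continuous variable
#'
#' Computes the Shapiro-Wilk p-value together with descriptive shape
#' statistics (sample skewness and excess kurtosis, SPSS-style type-2
#' estimators; coefficient of variation).  The verdict gates on the
#' Shapiro-Wilk test alone (`non_normal` iff p < alpha); the shape
#' statistics are reported for inspection, not combined into the
#' decision, so the verdict stays a deterministic function of one
#' statistic and one cutoff.
#'
#' @param x Numeric sample, n >= 3, non-constant.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return An object of class `normality_report` with fields
#'   `shapiro_p`, `skewness`, `kurtosis`, `coefficient_of_variation`,
#'   `verdict` (`"normal"` / `"non_normal"`) and `n`.
#' @export
assess_normality <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("normality assessment needs at least 3 values", call. = FALSE)
  if (anyNA(x)) stop("sample contains missing values", call. = FALSE)
  if (sd(x) == 0) stop("degenerate input: sample is constant", call. = FALSE)
  sw <- shapiro.test(x)
  cv <- if (mean(x) != 0) sd(x) / abs(mean(x)) else NA_real_
  structure(list(
    shapiro_p = sw$p.value,
    skewness = e1071::skewness(x, type = 2),
    kurtosis = e1071::kurtosis(x, type = 2),
    coefficient_of_variation = cv,
    verdict = if (sw$p.value < alpha) "non_normal" else "normal",
    n = length(x), alpha = alpha
  ), class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf("<normality_report> n=%d  Shapiro-Wilk p=%.4g  skew=%.3f  kurt=%.3f  CV=%.3f  -> %s\n",
              x$n, x$shapiro_p, x$skewness, x$kurtosis,
              x$coefficient_of_variation, x$verdict))
  invisible(x)
}

#' Log-transform a variable when screening flags it non-normal
#'
#' Applies the natural logarithm when the report's verdict is
#' `non_normal`, else returns the values unchanged.  Zeros or negative
#' values are handled by `log(x + c)` with `c` equal to the smallest
#' positive value observed in the sample; the offset is recorded so it
#' can be reported downstream.
#'
#' @param x Numeric sample.
#' @param report The [assess_normality()] report for `x`.
#' @return A list with `values`, `transformed` (flag) and `offset`
#'   (0 when no offset was needed).
#' @export
log_transform_if_needed <- function(x, report) {
  stopifnot(inherits(report, "normality_report"))
  if (report$verdict == "normal") {
    return(list(values = x, transformed = FALSE, offset = 0))
  }
  offset <- 0
  if (any(x <= 0)) {
    pos <- x[x > 0]
    if (!length(pos)) {
      stop("cannot log-transform: no positive values in sample", call. = FALSE)
    }
    offset <- min(pos)
  }
  list(values = log(x + offset), transformed = TRUE, offset = offset)
}

#' Pearson correlation with strength label
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform on n-2 degrees of freedom, labelled by conventional
#' absolute-strength bands.
#'
#' @param x,y Numeric vectors of equal length n >= 3, non-constant.
#' @param bands Upper edges of the |r| bands (right-closed), defaulting
#'   to 0.2/0.4/0.6/0.8/1 for very weak / weak / moderate / strong /
#'   very strong.
#' @return An object of class `correlation_result` with `r`, `p_value`,
#'   `n` and `strength_label`.
#' @export
pearson_correlation <- function(x, y, bands = c(0.2, 0.4, 0.6, 0.8, 1)) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("correlation needs at least 3 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("degenerate input: constant series has no defined correlation", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
                 strength_label = correlation_strength(unname(ct$estimate), bands)),
            class = "correlation_result")
}

#' @rdname pearson_correlation
#' @param r A correlation coefficient to label.
#' @export
correlation_strength <- function(r, bands = c(0.2, 0.4, 0.6, 0.8, 1)) {
  labels <- c("very weak", "weak", "moderate", "strong", "very strong")
  as.character(cut(abs(r), breaks = c(0, bands), labels = labels,
                   include.lowest = TRUE, right = TRUE))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r=%.3f (%s), p=%.4g, n=%d\n",
              x$r, x$strength_label, x$p_value, x$n))
  invisible(x)
}

#' Mann-Whitney U test for two independent groups
#'
#' U is computed from rank sums with midranks for ties.  The two-sided
#' p-value is exact (from the null distribution of U) when the groups
#' are tie-free and `n1 * n2 <= 400`; otherwise the normal
#' approximation with continuity and tie correction is used.  `method`
#' forces one route for comparison studies.
#'
#' @param a,b Numeric samples for the two groups (non-empty).
#' @param method `"auto"` (default), `"exact"` or `"approx"`.
#' @return An object of class `mw_test` with `u_statistic` (U of group
#'   `a`), `p_value`, `method`, and per-group medians and IQRs.
#' @export
mann_whitney_u <- function(a, b, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)                      # midranks for ties
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  use_exact <- switch(method,
    auto = !ties && n1 * n2 <= 400,
    exact = TRUE,
    approx = FALSE)
  if (use_exact && ties) {
    stop("exact p-value is undefined with ties; use method = 'approx'", call. = FALSE)
  }
  mu <- n1 * n2 / 2
  if (use_exact) {
    p <- if (u1 > mu) {
      2 * pwilcox(u1 - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * pwilcox(u1, n1, n2)
    }
    p <- min(1, p)
  } else {
    nn <- n1 + n2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1                              # all values identical
    } else {
      z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
      p <- min(1, p)
    }
  }
  iqr <- function(v) unname(quantile(v, 0.75) - quantile(v, 0.25))
  structure(list(u_statistic = u1, p_value = p,
                 method = if (use_exact) "exact" else "normal_approx",
                 n1 = n1, n2 = n2,
                 median_a = median(a), median_b = median(b),
                 iqr_a = iqr(a), iqr_b = iqr(b)),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<Mann-Whitney U> U=%g, p=%.4g (%s), n=%d/%d; medians %.3g vs %.3g\n",
              x$u_statistic, x$p_value, x$method, x$n1, x$n2,
              x$median_a, x$median_b))
  invisible(x)
}

#' Select regression predictors by correlation and collinearity screens
#'
#' Keeps candidates whose correlation with the outcome satisfies
#' `|r| > r_threshold` and `p < p_threshold`.  Then, for any surviving
#' pair whose mutual correlation exceeds `collinearity_threshold`
#' in absolute value, the member with the weaker outcome correlation is
#' dropped (ties broken by dropping the later one in the candidate
#' table's row order, which follows the standard parameter column
#' order).  All decisions are returned as a log.
#'
#' @param correlations Data frame with columns `parameter`, `r`, `p`,
#'   one row per candidate, rows in canonical parameter order.
#' @param intercorrelations Square correlation matrix of the candidates
#'   (dimnames matching `correlations$parameter`).
#' @param r_threshold,p_threshold,collinearity_threshold Screen
#'   cutoffs; defaults 0.25, 0.05, 0.80.
#' @return Character vector of selected parameter names, with
#'   attribute `"log"` describing each decision.
#' @export
select_predictors <- function(correlations, intercorrelations,
                              r_threshold = 0.25, p_threshold = 0.05,
                              collinearity_threshold = 0.80) {
  stopifnot(all(c("parameter", "r", "p") %in% names(correlations)))
  log <- character(0)
  keep <- correlations
  drop0 <- keep[!(abs(keep$r) > r_threshold & keep$p < p_threshold), "parameter"]
  if (length(drop0)) {
    log <- c(log, sprintf("excluded %s: |r| <= %.2f or p >= %.2f",
                          drop0, r_threshold, p_threshold))
  }
  keep <- keep[abs(keep$r) > r_threshold & keep$p < p_threshold, , drop = FALSE]
  # iterative collinearity pruning: always resolve the worst pair first
  repeat {
    if (nrow(keep) < 2L) break
    sel <- keep$parameter
    ic <- abs(intercorrelations[sel, sel, drop = FALSE])
    diag(ic) <- 0
    if (max(ic) <= collinearity_threshold) break
    worst <- which(ic == max(ic), arr.ind = TRUE)[1, ]
    p1 <- sel[worst[1]]; p2 <- sel[worst[2]]
    r1 <- abs(keep$r[keep$parameter == p1])
    r2 <- abs(keep$r[keep$parameter == p2])
    victim <- if (r1 < r2) p1 else if (r2 < r1) p2 else {
      # tie: drop the later in canonical order (row order of the table)
      sel[max(worst)]
    }
    log <- c(log, sprintf("dropped %s: |r|=%.2f with %s exceeds collinearity threshold %.2f (weaker outcome correlate)",
                          victim, max(ic), setdiff(c(p1, p2), victim),
                          collinearity_threshold))
    keep <- keep[keep$parameter != victim, , drop = FALSE]
  }
  out <- keep$parameter
  attr(out, "log") <- log
  out
}

#' Enter-method multiple linear regression
#'
#' Ordinary least squares with all selected predictors entered
#' simultaneously (no stepwise search).  Reports the coefficient table,
#' R-squared and adjusted R-squared, the overall F-test p-value, a
#' residual-normality summary, and an effect-size label from Cohen's
#' R-squared bands (0.02 small, 0.13 medium, 0.26 large).
#'
#' @param data Data frame holding outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names
#'   (typically from [select_predictors()]).
#' @return An object of class `enter_regression`.
#' @export
fit_linear_regression_enter <- function(data, outcome, predictors) {
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)))
  if (!length(predictors)) stop("no predictors to enter", call. = FALSE)
  if (nrow(data) <= length(predictors) + 1L) {
    stop("not enough observations for the number of predictors", call. = FALSE)
  }
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = sprintf("`%s`", outcome))
  fit <- lm(fml, data = data)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop(sprintf("rank-deficient design: predictor(s) %s are collinear with the others",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)
  r2 <- sm$r.squared
  fstat <- sm$fstatistic
  f_p <- if (!is.null(fstat)) {
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  } else NA_real_
  res <- stats::residuals(fit)
  res_shapiro <- if (length(res) >= 3 && length(res) <= 5000 && sd(res) > 0) {
    shapiro.test(res)$p.value
  } else NA_real_
  structure(list(
    outcome = outcome, predictors = predictors, fit = fit,
    coefficients = sm$coefficients,
    r_squared = r2, adjusted_r_squared = sm$adj.r.squared,
    f_p_value = f_p,
    residual_shapiro_p = res_shapiro,
    effect_size_label = cohen_r2_label(r2),
    n = nrow(data)
  ), class = "enter_regression")
}

#' Cohen's effect-size label for a model R-squared
#'
#' Bands: R-squared >= 0.26 large, >= 0.13 medium, >= 0.02 small,
#' below 0.02 negligible.
#'
#' @param r2 An R-squared value in \[0,1\].
#' @export
cohen_r2_label <- function(r2) {
  if (r2 >= 0.26) "large" else if (r2 >= 0.13) "medium"
  else if (r2 >= 0.02) "small" else "negligible"
}

#' @export
print.enter_regression <- function(x, ...) {
  cat(sprintf("<Enter regression> %s ~ %s\n", x$outcome,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  n=%d  R2=%.3f (adj %.3f, %s effect)  F-test p=%.4g\n",
              x$n, x$r_squared, x$adjusted_r_squared,
              x$effect_size_label, x$f_p_value))
  invisible(x)
}
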