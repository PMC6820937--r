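#' Precision and accuracy of a GFR estimator
#'
#' Summarises agreement between an estimator and measured aGFR: Pearson r
#' and r^2 (precision), RMSE, mean bias (mean of aGFR minus estimate) and
#' P30, the proportion of estimates within 30% of the measured value
#' (|estimate - aGFR| <= 0.30 aGFR, boundary inclusive).
#'
#' @param cohort A [gfr_cohort] with `agfr`, or a numeric vector of aGFR.
#' @param estimates Estimates aligned one-to-one with the aGFR values.
#' @return A list of class `gfr_eval`: `n`, `r`, `r_squared`, `rmse`,
#'   `bias`, `p30`.
#' @examples
#' evaluate_estimator(c(100, 120, 140), c(80, 100, 150))
#' @export
evaluate_estimator <- function(cohort, estimates) {
  agfr <- if (is.data.frame(cohort)) cohort$agfr else cohort
  if (length(agfr) == 0) stop("empty input", call. = FALSE)
  if (anyNA(agfr)) stop("agfr missing for some examinations", call. = FALSE)
  if (length(estimates) != length(agfr)) {
    stop("estimates must align one-to-one with aGFR values", call. = FALSE)
  }
  if (anyNA(estimates)) stop("estimates contain missing values",
                             call. = FALSE)
  n <- length(agfr)
  if (n < 3) stop("need at least 3 pairs for a correlation", call. = FALSE)
  r <- stats::cor(agfr, estimates)
  structure(list(n = n, r = r, r_squared = r^2,
                 rmse = sqrt(mean((estimates - agfr)^2)),
                 bias = mean(agfr - estimates),
                 p30 = mean(abs(estimates - agfr) <= 0.30 * agfr)),
            class = "gfr_eval")
}

#' @export
print.gfr_eval <- function(x, ...) {
  cat(sprintf(paste0("n = %d: r = %.3f (r^2 = %.3f), RMSE = %.2f, ",
                     "bias (aGFR - est) = %.2f, P30 = %.1f%%\n"),
              x$n, x$r, x$r_squared, x$rmse, x$bias, 100 * x$p30))
  invisible(x)
}

#' Compare two dependent, overlapping correlations
#'
#' Tests whether two estimators correlate equally with measured aGFR when
#' all three variables are observed on the same examinations. Uses the
#' Fisher-z test for overlapping dependent correlations of Meng, Rosenthal
#' & Rubin (Steiger family), which accounts for the correlation `r12`
#' between the two estimators. `n` is taken as the number of examinations;
#' with repeated measurements per subject this overstates the effective
#' sample size, so p-values on longitudinal data are anti-conservative
#' (noted in the returned object).
#'
#' @param agfr Measured aGFR values.
#' @param est1,est2 The two estimators, aligned with `agfr`.
#' @return A list of class `gfr_corr_comparison`: `r1`, `r2`, `r12`, `n`,
#'   `z`, `p_value`, and `note`.
#' @export
compare_dependent_correlations <- function(agfr, est1, est2) {
  n <- length(agfr)
  if (length(est1) != n || length(est2) != n) {
    stop("all three vectors must be aligned", call. = FALSE)
  }
  if (n < 10) stop("need n >= 10", call. = FALSE)
  r1 <- stats::cor(agfr, est1)
  r2 <- stats::cor(agfr, est2)
  r12 <- stats::cor(est1, est2)
  if (isTRUE(all.equal(est1, est2))) {
    # identical estimators: no difference to test
    return(structure(list(r1 = r1, r2 = r2, r12 = 1, n = n, z = 0,
                          p_value = 1,
                          note = "estimators are identical"),
                     class = "gfr_corr_comparison"))
  }
  if (any(abs(c(r1, r2, r12)) >= 1 - 1e-12)) {
    stop("degenerate input: a correlation is exactly +/-1", call. = FALSE)
  }
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min((1 - r12) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - r12) * h))
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(r1 = r1, r2 = r2, r12 = r12, n = n, z = z, p_value = p,
                 note = paste("n counts examinations; repeated measures",
                              "within subject make the test",
                              "anti-conservative")),
            class = "gfr_corr_comparison")
}

#' @export
print.gfr_corr_comparison <- function(x, ...) {
  cat(sprintf("r1 = %.3f vs r2 = %.3f (r12 = %.3f, n = %d): z = %.3f, p = %.3g\n",
              x$r1, x$r2, x$r12, x$n, x$z, x$p_value))
  cat("note:", x$note, "\n")
  invisible(x)
}

#' ROC curve for detecting hyperfiltration
#'
#' Labels each examination as hyperfiltering or not from the *measured*
#' aGFR (never from an estimator), sweeps classification thresholds over
#' the estimator values (midpoints between adjacent unique scores plus
#' infinite endpoints; predicted positive when estimate >= threshold), and
#' computes the AUC as the Mann-Whitney statistic with half credit for
#' ties.
#'
#' @param agfr Measured aGFR values (labels derive from these).
#' @param estimates Estimator scores aligned with `agfr`.
#' @param rule A [hyperfiltration_rule()].
#' @return A list of class `gfr_roc`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `n_pos`, `n_neg`, `rule`.
#' @export
roc_curve <- function(agfr, estimates, rule = hyperfiltration_rule()) {
  if (length(estimates) != length(agfr)) {
    stop("estimates must align with agfr", call. = FALSE)
  }
  labels <- classify_hyperfiltration(agfr, rule)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present (", n_pos, " positive, ", n_neg,
         " negative)", call. = FALSE)
  }
  u <- sort(unique(estimates))
  thresholds <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thresholds, function(t) mean(estimates[labels] >= t), 0)
  spec <- vapply(thresholds, function(t) mean(estimates[!labels] < t), 0)
  # AUC via midranks (Mann-Whitney with half credit for ties)
  rk <- rank(estimates)
  auc <- (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc, n_pos = n_pos,
                 n_neg = n_neg, rule = rule),
            class = "gfr_roc")
}

#' @export
print.gfr_roc <- function(x, ...) {
  cat(sprintf("ROC for hyperfiltration (aGFR %s %g): AUC = %.4f (%d+/%d-)\n",
              if (x$rule$comparison == "gt") ">" else ">=",
              x$rule$threshold, x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

# Placement values underlying the DeLong variance: for each positive, the
# fraction of negatives it beats (ties half); and vice versa.
delong_placements <- function(labels, scores) {
  pos <- scores[labels]; neg <- scores[!labels]
  v10 <- vapply(pos, function(s) mean(s > neg) + 0.5 * mean(s == neg), 0)
  v01 <- vapply(neg, function(s) mean(pos > s) + 0.5 * mean(pos == s), 0)
  list(v10 = v10, v01 = v01)
}

#' DeLong test for two correlated ROC areas
#'
#' Compares the AUCs of two estimators computed on the same examinations,
#' using the nonparametric covariance of DeLong, DeLong & Clarke-Pearson
#' derived from placement values.
#'
#' @inheritParams roc_curve
#' @param est1,est2 The two estimator score vectors.
#' @return A list of class `gfr_delong`: `auc1`, `auc2`, `var_diff`, `z`,
#'   `p_value`.
#' @export
delong_compare <- function(agfr, est1, est2,
                           rule = hyperfiltration_rule()) {
  if (length(est1) != length(agfr) || length(est2) != length(agfr)) {
    stop("score vectors must align with agfr", call. = FALSE)
  }
  labels <- classify_hyperfiltration(agfr, rule)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  p1 <- delong_placements(labels, est1)
  p2 <- delong_placements(labels, est2)
  auc1 <- mean(p1$v10); auc2 <- mean(p2$v10)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= 0 || isTRUE(all.equal(auc1, auc2))) {
    z <- 0
  } else {
    z <- (auc1 - auc2) / sqrt(var_diff)
  }
  structure(list(auc1 = auc1, auc2 = auc2, var_diff = var_diff, z = z,
                 p_value = if (z == 0) 1 else 2 * stats::pnorm(-abs(z))),
            class = "gfr_delong")
}

#' @export
print.gfr_delong <- function(x, ...) {
  cat(sprintf("DeLong: AUC1 = %.4f vs AUC2 = %.4f, z = %.3f, p = %.3g\n",
              x$auc1, x$auc2, x$z, x$p_value))
  invisible(x)
}

#' Threshold achieving a target specificity
#'
#' Finds the smallest threshold on the estimator scale whose specificity
#' reaches the target, and reports the sensitivity there. Useful for
#' screening statements such as "the threshold for detecting
#' hyperfiltration with 80% specificity".
#'
#' @param roc A `gfr_roc` from [roc_curve()].
#' @param target_spec Target specificity in (0, 1).
#' @return A list: `threshold`, `sensitivity`, `specificity` (achieved).
#' @export
threshold_at_specificity <- function(roc, target_spec) {
  stopifnot(inherits(roc, "gfr_roc"))
  if (!is.numeric(target_spec) || target_spec <= 0 || target_spec >= 1) {
    stop("target_spec must be in (0, 1)", call. = FALSE)
  }
  ok <- which(roc$specificity >= target_spec)
  ok <- ok[is.finite(roc$thresholds[ok])]
  if (length(ok) == 0) stop("no finite threshold reaches specificity ",
                            target_spec, call. = FALSE)
  i <- ok[which.min(roc$thresholds[ok])]
  list(threshold = roc$thresholds[i], sensitivity = roc$sensitivity[i],
       specificity = roc$specificity[i])
}

#' Mean estimation error by level of measured aGFR
#'
#' Splits examinations into equal-count (quantile) bins of measured aGFR
#' and reports the mean difference (aGFR minus estimate) per bin, exposing
#' level-dependent bias such as the systematic underestimation of high
#' measured GFR by creatinine-only equations.
#'
#' @inheritParams roc_curve
#' @param n_bins Number of quantile bins (default 10).
#' @return A list: `bins` (data frame with bin bounds, n, mean aGFR and
#'   mean difference per bin) and `overall_bias`.
#' @export
bias_by_level <- function(agfr, estimates, n_bins = 10) {
  if (length(estimates) != length(agfr)) {
    stop("estimates must align with agfr", call. = FALSE)
  }
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (length(agfr) < n_bins) stop("fewer points than bins", call. = FALSE)
  qs <- stats::quantile(agfr, probs = seq(0, 1, length.out = n_bins + 1),
                        type = 7)
  bin <- cut(agfr, breaks = unique(qs), include.lowest = TRUE)
  diff <- agfr - estimates
  bins <- data.frame(
    bin = levels(bin),
    n = as.vector(table(bin)),
    mean_agfr = as.vector(tapply(agfr, bin, mean)),
    mean_diff = as.vector(tapply(diff, bin, mean)),
    row.names = NULL)
  list(bins = bins, overall_bias = mean(diff))
}
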