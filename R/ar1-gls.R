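#' Linear model with AR(1) within-subject correlation
#'
#' Fits, by maximum likelihood, the marginal linear model
#' \deqn{y_{ij} = x_{ij}'\beta + e_{ij}, \qquad
#'       \mathrm{corr}(e_{ij}, e_{ik}) = \rho^{|j-k|}}
#' where `j` indexes a subject's examinations in order. This is the
#' longitudinal regression used throughout the derivation pipeline: fixed
#' effects plus a first-order autoregressive residual within subject,
#' indexed by exam order. Estimation is ML (not REML) so that AIC values
#' are comparable across fixed-effect sets during model selection.
#'
#' The AR(1) likelihood is evaluated in closed form by prewhitening each
#' subject's block (`e*_1 = e_1`, `e*_j = (e_j - rho e_{j-1}) /
#' sqrt(1 - rho^2)`), and `rho` is estimated by profile likelihood on
#' (-0.99, 0.99) to a tolerance of 1e-4. With a single exam per subject, or
#' `rho` fixed at 0, the fit reduces to ordinary least squares.
#'
#' @param cohort A [gfr_cohort]; needs `agfr` for the `log_agfr` and
#'   `diff_agfr_egfr` outcomes.
#' @param outcome `"log_agfr"` (natural log of measured aGFR), `"inv_scr"`
#'   (1/SCR, dL/mg) or `"diff_agfr_egfr"` (aGFR minus CKD-EPI eGFR).
#' @param covariates Character vector drawn from `age`, `sex`, `scr`,
#'   `bsa`, `duration`, `fpg10` (FPG per 10 mg/dL), `hba1c`.
#' @param rho Optional fixed value for the autocorrelation; `NULL`
#'   (default) profiles it.
#' @return An object of class `gfr_lmm`: coefficient table (estimate, SE,
#'   z, p), `sigma` (residual sd), `rho`, `loglik`, `aic`, `n_obs`,
#'   `n_subjects`, `n_par`, `r_squared` (squared correlation of the fixed
#'   linear predictor with the outcome), plus `fitted` and `outcome`.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(generative_config(n_subjects = 60,
#'                                          total_exams = 600), seed = 1)
#' fit_lmm_ar1(coh, "log_agfr", c("age", "sex", "scr", "fpg10", "hba1c"))
#' }
#' @export
fit_lmm_ar1 <- function(cohort,
                        outcome = c("log_agfr", "inv_scr", "diff_agfr_egfr"),
                        covariates, rho = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(is.data.frame(cohort))
  if (length(unique(cohort$subject_id)) < 2) {
    stop("fit_lmm_ar1() needs at least 2 subjects", call. = FALSE)
  }
  y <- outcome_vector(cohort, outcome)
  X <- design_matrix(cohort, covariates)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2) stop("fewer observations than parameters", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular design; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  ord <- order(cohort$subject_id, cohort$exam_index)
  y <- y[ord]; X <- X[ord, , drop = FALSE]
  sid <- cohort$subject_id[ord]
  first <- !duplicated(sid)       # TRUE at each subject's first exam
  n_rep <- sum(!first)            # rows carrying an AR(1) lag term

  prof <- function(r) ar1_profile_loglik(y, X, first, r)
  if (!is.null(rho)) {
    stopifnot(is.numeric(rho), length(rho) == 1, abs(rho) < 1)
    rho_hat <- rho
  } else if (n_rep == 0) {
    rho_hat <- 0                  # one exam per subject: rho unidentified
  } else {
    opt <- stats::optimize(function(r) -prof(r)$loglik,
                           interval = c(-0.99, 0.99), tol = 1e-4)
    rho_hat <- opt$minimum
  }
  fit <- prof(rho_hat)
  beta <- fit$beta
  # model-based SEs at rho_hat, with the usual n - p variance correction
  XtXinv <- chol2inv(chol(crossprod(fit$Xw)))
  s2_adj <- fit$rss / (n - p)
  se <- sqrt(diag(XtXinv) * s2_adj)
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  n_par <- p + 2L                 # beta, sigma^2, rho
  aic <- -2 * fit$loglik + 2 * n_par
  lp <- drop(X %*% beta)
  res <- structure(list(
    outcome = outcome,
    covariates = colnames(X)[-1],
    coefficients = data.frame(term = colnames(X), estimate = beta,
                              se = se, z = zval, p_value = pval,
                              row.names = NULL),
    sigma = sqrt(fit$rss / n),
    rho = rho_hat,
    loglik = fit$loglik,
    aic = aic,
    n_par = n_par,
    n_obs = n,
    n_subjects = length(unique(sid)),
    r_squared = stats::cor(lp, y)^2,
    fitted = lp[order(ord)],
    rho_profiled = is.null(rho)
  ), class = "gfr_lmm")
  res
}

# Profile log-likelihood pieces at a given rho: whitened design, GLS beta,
# whitened RSS and the ML log-likelihood (sigma^2 profiled out).
ar1_profile_loglik <- function(y, X, first, rho) {
  n <- length(y)
  a <- sqrt(1 - rho^2)
  lag <- c(NA, y[-n]); lagX <- rbind(NA, X[-n, , drop = FALSE])
  yw <- ifelse(first, y, (y - rho * lag) / a)
  Xw <- X
  rep_rows <- which(!first)
  if (length(rep_rows)) {
    Xw[rep_rows, ] <- (X[rep_rows, , drop = FALSE] -
                       rho * lagX[rep_rows, , drop = FALSE]) / a
  }
  f <- stats::lm.fit(Xw, yw)
  rss <- sum(f$residuals^2)
  s2 <- rss / n
  # log|R| summed over subjects: (n_i - 1) log(1 - rho^2) each
  ldet <- length(rep_rows) * log(1 - rho^2)
  loglik <- -n / 2 * (log(2 * pi * s2) + 1) - ldet / 2
  list(beta = stats::setNames(f$coefficients, colnames(X)),
       rss = rss, Xw = Xw, loglik = loglik)
}

outcome_vector <- function(cohort, outcome) {
  switch(outcome,
    log_agfr = {
      if (anyNA(cohort$agfr)) stop("agfr missing; cannot form log_agfr",
                                   call. = FALSE)
      log(cohort$agfr)
    },
    inv_scr = 1 / cohort$scr,
    diff_agfr_egfr = {
      if (anyNA(cohort$agfr)) stop("agfr missing; cannot form diff_agfr_egfr",
                                   call. = FALSE)
      cohort$agfr - ckd_epi(cohort$sex, cohort$age, cohort$scr)
    })
}

LMM_COVARIATES <- c("age", "sex", "scr", "bsa", "duration", "fpg10", "hba1c")

design_matrix <- function(cohort, covariates) {
  bad <- setdiff(covariates, LMM_COVARIATES)
  if (length(bad)) {
    stop("unknown covariate(s): ", paste(bad, collapse = ", "),
         "; choose from ", paste(LMM_COVARIATES, collapse = ", "),
         call. = FALSE)
  }
  cols <- list("(Intercept)" = rep(1, nrow(cohort)))
  for (v in covariates) {
    cols[[switch(v, sex = "sex_female", v)]] <- switch(v,
      age = cohort$age,
      sex = as.numeric(cohort$sex == "female"),
      scr = cohort$scr,
      bsa = dubois_bsa(cohort$height, cohort$weight),
      duration = {
        if (anyNA(cohort$duration)) stop("duration missing for some exams",
                                         call. = FALSE)
        cohort$duration
      },
      fpg10 = cohort$fpg / 10,
      hba1c = cohort$hba1c)
  }
  do.call(cbind, cols)
}

#' @export
print.gfr_lmm <- function(x, ...) {
  cat(sprintf("AR(1) marginal linear model (ML), outcome = %s\n", x$outcome))
  cat(sprintf("n = %d exams, %d subjects; rho = %.4f, sigma = %.4f\n",
              x$n_obs, x$n_subjects, x$rho, x$sigma))
  cat(sprintf("logLik = %.3f, AIC = %.3f, marginal r^2 = %.4f\n",
              x$loglik, x$aic, x$r_squared))
  stats::printCoefmat(cbind(Estimate = x$coefficients$estimate,
                     `Std.Error` = x$coefficients$se,
                     `z value` = x$coefficients$z,
                     `Pr(>|z|)` = x$coefficients$p_value),
               P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Exhaustive AIC model selection over covariate subsets
#'
#' Fits every non-empty subset of `candidate_vars` (2^k - 1 models) with
#' [fit_lmm_ar1()] and ranks them by AIC. Ties are broken toward fewer
#' variables, then lexicographically. Subsets are enumerated by size, then
#' lexicographically, so the reported table order is deterministic.
#'
#' @inheritParams fit_lmm_ar1
#' @param candidate_vars Candidate covariates (at most 10).
#' @return A list with `best` (the minimum-AIC `gfr_lmm`), `best_vars`, and
#'   `table` (one row per subset: variables, k, AIC, logLik, error message
#'   for subsets whose fit failed).
#' @export
select_model_aic <- function(cohort, outcome, candidate_vars) {
  stopifnot(length(candidate_vars) >= 1)
  if (length(candidate_vars) > 10) {
    stop("at most 10 candidate variables (exhaustive enumeration)",
         call. = FALSE)
  }
  candidate_vars <- sort(unique(candidate_vars))
  subsets <- list()
  for (k in seq_along(candidate_vars)) {
    cmb <- utils::combn(candidate_vars, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  fits <- vector("list", length(subsets))
  tab <- data.frame(variables = vapply(subsets, paste, "", collapse = "+"),
                    k = vapply(subsets, length, 0L),
                    aic = NA_real_, loglik = NA_real_,
                    error = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(subsets)) {
    f <- tryCatch(fit_lmm_ar1(cohort, outcome, subsets[[i]]),
                  error = function(e) e)
    if (inherits(f, "error")) {
      tab$error[i] <- conditionMessage(f)
    } else {
      fits[[i]] <- f
      tab$aic[i] <- f$aic
      tab$loglik[i] <- f$loglik
    }
  }
  if (all(is.na(tab$aic))) {
    stop("all candidate subsets failed to fit", call. = FALSE)
  }
  # enumeration order is (size, lexicographic): which.min realises the
  # documented tie-break
  best_i <- which.min(tab$aic)
  list(best = fits[[best_i]], best_vars = subsets[[best_i]],
       table = tab[order(tab$aic), ])
}

#' Model for the gap between measured aGFR and CKD-EPI eGFR
#'
#' Fits `aGFR - eGFR(CKD-EPI)` on sex, age, SCR, FPG (per 10 mg/dL), HbA1c
#' and diabetes duration with [fit_lmm_ar1()]. Positive glycemia
#' coefficients indicate that the creatinine-only equation underestimates
#' measured GFR more severely under hyperglycemia.
#'
#' @inheritParams fit_lmm_ar1
#' @param covariates Covariates for the difference model.
#' @return A `gfr_lmm`.
#' @export
difference_model <- function(cohort,
                             covariates = c("sex", "age", "scr", "fpg10",
                                            "hba1c", "duration")) {
  fit_lmm_ar1(cohort, "diff_agfr_egfr", covariates)
}
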