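#' Per-sex serum-creatinine quartile cut points
#'
#' Computes, separately for men and women, the quartile cut points of SCR
#' over examinations (not subjects), using linear interpolation between
#' order statistics (`stats::quantile` type 7). Together with sex these
#' define the eight strata of the approximating equations; stratifying on
#' SCR absorbs the nonlinearity of GFR in creatinine that a single
#' log-linear equation cannot capture.
#'
#' @param cohort A [gfr_cohort].
#' @param sexes Sexes to compute (default: those present in the cohort).
#' @return Named list (per sex) of the three cut points. If a sex's SCR
#'   values are all identical the cut points are degenerate and downstream
#'   stratification collapses to a single stratum (with a warning).
#' @export
scr_quartile_cutpoints <- function(cohort, sexes = unique(cohort$sex)) {
  stopifnot(is.data.frame(cohort))
  out <- list()
  for (sx in sexes) {
    scr <- cohort$scr[cohort$sex == sx]
    if (length(scr) == 0) stop("no examinations for sex ", sx, call. = FALSE)
    if (length(scr) < 4) stop("need at least 4 exams per sex; sex ", sx,
                              " has ", length(scr), call. = FALSE)
    out[[sx]] <- unname(stats::quantile(scr, c(0.25, 0.5, 0.75), type = 7))
  }
  out
}

cutpoints_to_strata <- function(cutpoints) {
  rows <- lapply(names(cutpoints), function(sx) {
    q <- cutpoints[[sx]]
    if (anyDuplicated(q)) {
      warning("degenerate SCR cut points for sex ", sx,
              "; collapsing to a single stratum", call. = FALSE)
      return(data.frame(sex = sx, scr_lo = 0, scr_hi = Inf))
    }
    data.frame(sex = sx, scr_lo = c(0, q), scr_hi = c(q, Inf))
  })
  do.call(rbind, rows)
}

#' Fit stratified log-linear approximating equations
#'
#' Within each sex-by-SCR-quartile stratum, regresses log aGFR on the
#' scaled covariates (by default age/10, HbA1c, FPG/100, SCR) by ordinary
#' least squares, and assembles the per-stratum intercepts and coefficients
#' into a [equation_spec()]. OLS is used because these are prediction
#' equations: no within-stratum inference is drawn from them. A mixed-fit
#' variant (AR(1) residuals, via [fit_lmm_ar1()]) is available with
#' `method = "ar1"`.
#'
#' @param cohort A [gfr_cohort] with `agfr` present.
#' @param cutpoints Per-sex cut points from [scr_quartile_cutpoints()].
#' @param variables Covariates entering each stratum equation.
#' @param scaling Named divisors applied to covariates before fitting; the
#'   fitted coefficients are recorded on the scaled variables.
#' @param method `"ols"` (default) or `"ar1"`.
#' @param name Name for the resulting spec.
#' @return A `gfr_equation_spec`.
#' @export
fit_stratified_equations <- function(cohort, cutpoints,
                                     variables = c("age", "hba1c", "fpg",
                                                   "scr"),
                                     scaling = c(age = 10, hba1c = 1,
                                                 fpg = 100, scr = 1),
                                     method = c("ols", "ar1"),
                                     name = "derived") {
  method <- match.arg(method)
  stopifnot(is.data.frame(cohort))
  if (anyNA(cohort$agfr)) stop("agfr required to derive equations",
                               call. = FALSE)
  scaling <- scaling[variables]
  if (anyNA(scaling)) stop("scaling must cover every variable", call. = FALSE)
  strata <- cutpoints_to_strata(cutpoints)
  coef_mat <- matrix(NA_real_, nrow(strata), length(variables) + 1,
                     dimnames = list(NULL, c("intercept", variables)))
  for (i in seq_len(nrow(strata))) {
    sel <- cohort$sex == strata$sex[i] &
      cohort$scr >= strata$scr_lo[i] & cohort$scr < strata$scr_hi[i]
    sub <- cohort[sel, , drop = FALSE]
    if (nrow(sub) <= length(variables) + 1) {
      stop("stratum ", strata$sex[i], " [", strata$scr_lo[i], ", ",
           strata$scr_hi[i], ") has too few exams (", nrow(sub), ")",
           call. = FALSE)
    }
    Xs <- vapply(variables, function(v) sub[[v]] / scaling[[v]],
                 numeric(nrow(sub)))
    if (method == "ols") {
      fit <- stats::lm.fit(cbind(1, Xs), log(sub$agfr))
      coef_mat[i, ] <- fit$coefficients
    } else {
      lf <- fit_lmm_ar1_scaled(sub, variables, scaling)
      coef_mat[i, ] <- lf
    }
  }
  st <- cbind(strata, as.data.frame(coef_mat))
  equation_spec(name, st, scaling)
}

# AR(1) fit of log aGFR on manually scaled covariates (used by the
# method = "ar1" variant, where the standard design builder's units do not
# apply).
fit_lmm_ar1_scaled <- function(sub, variables, scaling) {
  tmp <- sub
  for (v in variables) tmp[[v]] <- tmp[[v]] / scaling[[v]]
  # reuse the AR(1) machinery directly on the scaled columns
  y <- log(tmp$agfr)
  X <- cbind("(Intercept)" = rep(1, nrow(tmp)),
             vapply(variables, function(v) tmp[[v]], numeric(nrow(tmp))))
  ord <- order(tmp$subject_id, tmp$exam_index)
  y <- y[ord]; X <- X[ord, , drop = FALSE]
  first <- !duplicated(tmp$subject_id[ord])
  opt <- stats::optimize(
    function(r) -ar1_profile_loglik(y, X, first, r)$loglik,
    interval = c(-0.99, 0.99), tol = 1e-4)
  ar1_profile_loglik(y, X, first, opt$minimum)$beta
}

#' Subject-level fold assignment
#'
#' Randomly partitions subjects (not examinations) into `k` folds whose
#' sizes differ by at most one, so that all of a subject's exams share a
#' fold and no subject's data can leak between training and test splits.
#'
#' @param cohort A [gfr_cohort].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle (required, so assignments
#'   are reproducible and loggable).
#' @return Named integer vector: subject id -> fold in `1..k`.
#' @export
assign_folds <- function(cohort, k = 10, seed) {
  stopifnot(is.data.frame(cohort))
  if (missing(seed)) stop("assign_folds() requires an explicit seed",
                          call. = FALSE)
  subjects <- sort(unique(cohort$subject_id))
  if (k > length(subjects)) {
    stop("k = ", k, " exceeds the number of subjects (", length(subjects),
         ")", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  shuffled <- sample(subjects)
  folds <- rep_len(seq_len(k), length(subjects))
  stats::setNames(folds[match(subjects, shuffled)], subjects)
}

#' Derive approximating equations by subject-level cross-validation
#'
#' Runs the full derivation loop: subjects are split into `k` folds; for
#' each fold, SCR quartile cut points and stratified equations are
#' estimated on the training 90% only (cut points re-estimated per fold,
#' so no information from held-out subjects enters the training fit), and
#' approximated GFR is predicted for the held-out subjects' exams. Every
#' exam therefore receives exactly one out-of-fold prediction. The final
#' reported spec averages the `k` training specs stratum by stratum
#' (strata aligned by their rank within sex; cut points averaged).
#'
#' @inheritParams assign_folds
#' @inheritParams fit_stratified_equations
#' @return A list of class `gfr_cv`: `final_spec`, `fold_specs`,
#'   `oof_predictions` (aligned to `cohort` rows), `folds`, `k`, `seed`.
#' @export
cross_validate <- function(cohort, k = 10, seed,
                           variables = c("age", "hba1c", "fpg", "scr"),
                           scaling = c(age = 10, hba1c = 1, fpg = 100,
                                       scr = 1),
                           method = c("ols", "ar1")) {
  method <- match.arg(method)
  folds <- assign_folds(cohort, k, seed)
  exam_fold <- folds[cohort$subject_id]
  oof <- rep(NA_real_, nrow(cohort))
  fold_specs <- vector("list", k)
  for (f in seq_len(k)) {
    train <- cohort[exam_fold != f, , drop = FALSE]
    test <- cohort[exam_fold == f, , drop = FALSE]
    cuts <- scr_quartile_cutpoints(train)
    spec <- tryCatch(
      fit_stratified_equations(train, cuts, variables, scaling, method,
                               name = sprintf("fold%02d", f)),
      error = function(e) {
        stop("fold ", f, ": ", conditionMessage(e),
             " (consider fewer strata or larger folds)", call. = FALSE)
      })
    fold_specs[[f]] <- spec
    if (nrow(test)) oof[exam_fold == f] <- predict_equation(spec, test)
  }
  structure(list(final_spec = average_specs(fold_specs, name = "cv-final"),
                 fold_specs = fold_specs, oof_predictions = oof,
                 folds = folds, k = k, seed = seed),
            class = "gfr_cv")
}

#' Average equation specs stratum by stratum
#'
#' Strata are aligned by their rank within sex (all specs must share the
#' same stratum layout); intercepts, coefficients and interval cut points
#' are arithmetic means across specs.
#'
#' @param specs List of `gfr_equation_spec` objects.
#' @param name Name for the averaged spec.
#' @return A `gfr_equation_spec`.
#' @export
average_specs <- function(specs, name = "averaged") {
  stopifnot(length(specs) >= 1)
  ref <- specs[[1]]
  for (s in specs) {
    if (!identical(dim(s$strata), dim(ref$strata)) ||
        !identical(s$strata$sex, ref$strata$sex) ||
        !identical(s$variables, ref$variables)) {
      stop("specs have incompatible stratum layouts", call. = FALSE)
    }
    if (!identical(s$scaling, ref$scaling)) {
      stop("specs have different scalings", call. = FALSE)
    }
  }
  num_cols <- c("scr_lo", "scr_hi", "intercept", ref$variables)
  st <- ref$strata
  for (cc in num_cols) {
    st[[cc]] <- rowMeans(vapply(specs, function(s) s$strata[[cc]],
                                numeric(nrow(st))))
  }
  equation_spec(name, st, ref$scaling)
}

#' @export
print.gfr_cv <- function(x, ...) {
  cat(sprintf("<gfr_cv> %d-fold subject-level cross-validation (seed %s)\n",
              x$k, format(x$seed)))
  cat(sprintf("out-of-fold predictions: %d exams\n",
              sum(!is.na(x$oof_predictions))))
  print(x$final_spec)
  invisible(x)
}
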