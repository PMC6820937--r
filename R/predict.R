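#' Add GFR estimate columns to a cohort
#'
#' Convenience wrapper used by the command-line `predict` subcommand:
#' evaluates built-in creatinine equations and/or stratified approximating
#' equation specs on every examination and returns the cohort with one new
#' column per estimator.
#'
#' @param cohort A [gfr_cohort].
#' @param builtins Character subset of `"ckd_epi"`, `"mdrd"`, `"bsa"`.
#' @param specs Named list of `gfr_equation_spec` objects; the names become
#'   column names (prefixed `approx_`). The shipped equations are available
#'   as `list(pima = pima_equations())`.
#' @param strict If `TRUE`, a spec whose covariates are missing aborts;
#'   otherwise its column is filled with `NA` and a warning is raised.
#' @return The cohort data frame with estimate columns appended.
#' @export
predict_cohort <- function(cohort, builtins = c("ckd_epi", "mdrd"),
                           specs = list(), strict = TRUE) {
  stopifnot(is.data.frame(cohort))
  builtins <- if (length(builtins)) {
    match.arg(builtins, c("ckd_epi", "mdrd", "bsa"), several.ok = TRUE)
  } else character(0)
  out <- cohort
  for (b in builtins) {
    out[[paste0("est_", b)]] <- switch(b,
      ckd_epi = ckd_epi(cohort$sex, cohort$age, cohort$scr),
      mdrd = mdrd(cohort$sex, cohort$age, cohort$scr),
      bsa = dubois_bsa(cohort$height, cohort$weight))
  }
  if (length(specs)) {
    if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
      stop("specs must be a named list", call. = FALSE)
    }
    for (nm in names(specs)) {
      col <- paste0("approx_", nm)
      pred <- tryCatch(predict_equation(specs[[nm]], cohort),
                       error = function(e) e)
      if (inherits(pred, "error")) {
        if (strict) stop(conditionMessage(pred), call. = FALSE)
        warning("spec '", nm, "': ", conditionMessage(pred),
                "; filling NA", call. = FALSE)
        pred <- rep(NA_real_, nrow(cohort))
      }
      out[[col]] <- pred
    }
  }
  out
}
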