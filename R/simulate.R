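#' Configuration for the synthetic longitudinal diabetic cohort generator
#'
#' Bundles every parameter of the simulator. The defaults emulate a
#' longitudinal cohort of adults with type 2 diabetes and repeated
#' iothalamate GFR studies: 269 subjects contributing 2798 eligible
#' examinations, with roughly 70% of exams from women, mean inter-exam gap
#' 3.3 +/- 1.9 years, and per-sex covariate moments (FPG, HbA1c, height,
#' weight, serum creatinine, measured aGFR) matching the published cohort
#' description. The generative skeleton is a pair of published mixed-model
#' regressions: 1/SCR is drawn from a linear model on sex, age, HbA1c and
#' FPG, and log aGFR from a linear model on sex, age, SCR, FPG and HbA1c,
#' each with a stationary AR(1) residual across a subject's successive
#' exams. FPG and HbA1c are drawn as a correlated Gaussian pair (target
#' exam-level correlation 0.71) with a between-/within-subject variance
#' split and AR(1) persistence of the within-subject part.
#'
#' Residual standard deviations and the baseline-age constants are
#' calibration choices: they were fixed, once, so that the fitted
#' age+sex+SCR model explains about 44.8% of log-aGFR variance (with FPG
#' and HbA1c adding about 2.7 points), and so that exam-level SCR spread
#' and mean ages match the published per-sex values. See the package
#' vignette for the derivation of each constant.
#'
#' @param n_subjects Number of subjects (default 269).
#' @param total_exams Eligible examinations in the returned cohort
#'   (default 2798).
#' @param sex_ratio Probability a subject is a woman (default 1948/2798,
#'   the women's share of examinations).
#' @param exam_count_range Inclusive integer range from which each
#'   subject's raw exam count is drawn uniformly (default 7..15; the total
#'   is then trimmed/topped up to `total_exams`).
#' @param gap_mean,gap_sd Mean and sd (years) of the lognormal inter-exam
#'   gap distribution (defaults 3.3 and 1.9).
#' @param baseline_age_mean,baseline_age_sd,baseline_age_range Per-sex
#'   truncated-normal baseline (first-exam) age model; the defaults place
#'   exam-level mean ages near 49.4 (men) / 48.5 (women) after the
#'   longitudinal offset accrued over repeated exams.
#' @param covariate_moments Per-sex means/sds for FPG (mg/dL), HbA1c (%),
#'   height (m) and weight (kg).
#' @param between_frac Fraction of covariate variance placed between
#'   subjects (default 2/3; the rest is within-subject AR(1) variation).
#' @param glycemia_correlation Target FPG-HbA1c correlation (default 0.71),
#'   applied to both the between- and within-subject components.
#' @param ar1_rho Lag-1 autocorrelation (per exam step) of every
#'   within-subject process (default 0.6).
#' @param scr_model Coefficients of the generative 1/SCR (dL/mg) model.
#' @param scr_resid_sd Per-sex stationary sd of the 1/SCR AR(1) residual.
#' @param agfr_model Coefficients of the generative log-aGFR model.
#' @param agfr_resid_sd Stationary sd of the log-aGFR AR(1) residual.
#' @param baseline_duration_mean,baseline_duration_sd Truncated-normal
#'   (>= 0) diabetes duration at first exam; duration then advances with
#'   the exam gaps.
#' @param scr_floor,scr_cap,fpg_min,hba1c_range,weight_min Physiological
#'   guard rails applied after Gaussian sampling.
#' @param eligibility_threshold Exams with CKD-EPI eGFR below this are
#'   dropped during generation (default 60).
#' @param max_attempts Bound on regeneration attempts before the
#'   configuration is declared unreachable.
#' @return A list of class `gfr_generative_config`.
#' @export
generative_config <- function(
    n_subjects = 269,
    total_exams = 2798,
    sex_ratio = 1948 / 2798,
    exam_count_range = c(7L, 15L),
    gap_mean = 3.3, gap_sd = 1.9,
    baseline_age_mean = c(male = 32.4, female = 31.5),
    baseline_age_sd = 7,
    baseline_age_range = c(18, 60),
    covariate_moments = list(
      fpg = list(mean = c(male = 190.9, female = 214.3),
                 sd = c(male = 77.5, female = 85.7)),
      hba1c = list(mean = c(male = 9.0, female = 9.7),
                   sd = c(male = 2.3, female = 2.2)),
      height = list(mean = c(male = 1.718, female = 1.606),
                    sd = c(male = 0.059, female = 0.060)),
      weight = list(mean = c(male = 99.3, female = 94.0),
                    sd = c(male = 26.2, female = 23.4))),
    between_frac = 2 / 3,
    glycemia_correlation = 0.71,
    ar1_rho = 0.6,
    scr_model = c(intercept = 1.4931, sex_female = 0.2821, age = -0.0082,
                  hba1c = 0.0287, fpg10 = -0.0043),
    scr_resid_sd = c(male = 0.29, female = 0.35),
    agfr_model = c(intercept = 5.8502, sex_female = -0.2151, age = -0.0100,
                   scr = -0.8639, fpg10 = 0.0061, hba1c = 0.0061),
    agfr_resid_sd = 0.237,
    baseline_duration_mean = 0, baseline_duration_sd = 4,
    scr_floor = 0.3, scr_cap = 8,
    fpg_min = 40, hba1c_range = c(4.5, 18), weight_min = 35,
    eligibility_threshold = 60,
    max_attempts = 500) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_subjects >= 1, cfg$total_exams >= cfg$n_subjects,
            cfg$sex_ratio > 0, cfg$sex_ratio < 1,
            cfg$gap_mean > 0, cfg$gap_sd >= 0,
            abs(cfg$glycemia_correlation) < 1,
            cfg$ar1_rho >= 0, cfg$ar1_rho < 1,
            cfg$agfr_resid_sd >= 0, all(cfg$scr_resid_sd >= 0),
            cfg$between_frac > 0, cfg$between_frac < 1)
  class(cfg) <- "gfr_generative_config"
  cfg
}

#' Override generative coefficients (parameter-recovery harness)
#'
#' Returns a copy of `config` with named generative parameters replaced.
#' Coefficients inside the regression skeletons are addressed as
#' `"agfr_model.<term>"` / `"scr_model.<term>"` (e.g.
#' `"agfr_model.fpg10"`); scalar parameters by their config name (e.g.
#' `"ar1_rho"`, `"glycemia_correlation"`, `"agfr_resid_sd"`).
#'
#' @param config A [generative_config()].
#' @param overrides Named numeric vector or list of replacements.
#' @return The modified config.
#' @examples
#' cfg <- inject_known_effects(generative_config(),
#'                             c(agfr_model.fpg10 = 0,
#'                               agfr_model.hba1c = 0))
#' @export
inject_known_effects <- function(config, overrides) {
  stopifnot(inherits(config, "gfr_generative_config"))
  overrides <- unlist(overrides)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
    stop("overrides must be named", call. = FALSE)
  }
  for (nm in names(overrides)) {
    val <- as.numeric(overrides[[nm]])
    if (grepl("\\.", nm)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      model <- parts[1]; term <- parts[2]
      if (!model %in% c("agfr_model", "scr_model") ||
          !term %in% names(config[[model]])) {
        stop("unknown generative coefficient: ", nm, call. = FALSE)
      }
      config[[model]][[term]] <- val
    } else {
      if (!nm %in% names(config) || !is.numeric(config[[nm]]) ||
          length(config[[nm]]) != 1) {
        stop("unknown generative parameter: ", nm, call. = FALSE)
      }
      config[[nm]] <- val
    }
  }
  config
}

# inverse-CDF truncated normal (uses exactly one uniform per draw)
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# stationary AR(1) path of length n with marginal sd `sd`, given innovation
# z-scores (standard normal)
ar1_path <- function(z, rho, sd) {
  n <- length(z)
  x <- numeric(n)
  x[1] <- z[1] * sd
  if (n > 1) {
    a <- sd * sqrt(1 - rho^2)
    for (j in 2:n) x[j] <- rho * x[j - 1] + a * z[j]
  }
  x
}

# pair of standard-normal innovation streams with correlation r
correlated_z <- function(n, r) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cbind(z1, r * z1 + sqrt(1 - r^2) * z2)
}

simulate_subject <- function(id, sex, n, cfg) {
  mom <- cfg$covariate_moments
  bf <- cfg$between_frac
  rho <- cfg$ar1_rho
  base_age <- rtruncnorm(1, cfg$baseline_age_mean[[sex]],
                         cfg$baseline_age_sd,
                         cfg$baseline_age_range[1], cfg$baseline_age_range[2])
  gaps <- if (n > 1) {
    m <- cfg$gap_mean; s <- cfg$gap_sd
    sdlog <- sqrt(log(1 + (s / m)^2))
    stats::rlnorm(n - 1, log(m) - sdlog^2 / 2, sdlog)
  } else numeric(0)
  age <- base_age + cumsum(c(0, gaps))
  height <- rtruncnorm(1, mom$height$mean[[sex]], mom$height$sd[[sex]],
                       1.3, 2.1)
  wt_b <- stats::rnorm(1, 0, mom$weight$sd[[sex]] * sqrt(bf))
  wt_w <- ar1_path(stats::rnorm(n), rho,
                   mom$weight$sd[[sex]] * sqrt(1 - bf))
  weight <- pmax(mom$weight$mean[[sex]] + wt_b + wt_w, cfg$weight_min)
  # FPG/HbA1c: correlated between-subject levels + correlated AR(1)
  # within-subject deviations -> exam-level correlation ~ target
  r <- cfg$glycemia_correlation
  zb <- correlated_z(1, r)
  fpg_b <- zb[1] * mom$fpg$sd[[sex]] * sqrt(bf)
  a1c_b <- zb[2] * mom$hba1c$sd[[sex]] * sqrt(bf)
  zw <- correlated_z(n, r)
  fpg_w <- ar1_path(zw[, 1], rho, mom$fpg$sd[[sex]] * sqrt(1 - bf))
  a1c_w <- ar1_path(zw[, 2], rho, mom$hba1c$sd[[sex]] * sqrt(1 - bf))
  fpg <- pmax(mom$fpg$mean[[sex]] + fpg_b + fpg_w, cfg$fpg_min)
  hba1c <- pmin(pmax(mom$hba1c$mean[[sex]] + a1c_b + a1c_w,
                     cfg$hba1c_range[1]), cfg$hba1c_range[2])
  female <- as.numeric(sex == "female")
  sm <- cfg$scr_model
  inv_resid <- ar1_path(stats::rnorm(n), rho, cfg$scr_resid_sd[[sex]])
  inv_scr <- sm[["intercept"]] + sm[["sex_female"]] * female +
    sm[["age"]] * age + sm[["hba1c"]] * hba1c + sm[["fpg10"]] * fpg / 10 +
    inv_resid
  scr <- pmin(pmax(1 / pmax(inv_scr, 1 / cfg$scr_cap), cfg$scr_floor),
              cfg$scr_cap)
  am <- cfg$agfr_model
  agfr_resid <- ar1_path(stats::rnorm(n), rho, cfg$agfr_resid_sd)
  log_agfr <- am[["intercept"]] + am[["sex_female"]] * female +
    am[["age"]] * age + am[["scr"]] * scr + am[["fpg10"]] * fpg / 10 +
    am[["hba1c"]] * hba1c + agfr_resid
  agfr <- exp(log_agfr)
  duration <- rtruncnorm(1, cfg$baseline_duration_mean,
                         cfg$baseline_duration_sd, 0, Inf) +
    cumsum(c(0, gaps))
  bsa <- dubois_bsa(height, weight)
  data.frame(subject_id = id, exam_index = seq_len(n), age = age, sex = sex,
             height = height, weight = weight, scr = scr, fpg = fpg,
             hba1c = hba1c, duration = duration,
             mgfr = agfr * bsa / 1.73, agfr = agfr,
             .inv_scr_resid = inv_resid, .log_agfr_resid = agfr_resid,
             stringsAsFactors = FALSE)
}

# keep only exams passing the eligibility screen
eligible_rows <- function(df, cfg) {
  ckd_epi(df$sex, df$age, df$scr) >= cfg$eligibility_threshold
}

#' Simulate a synthetic longitudinal diabetic cohort
#'
#' Generates `config$n_subjects` subjects and exactly `config$total_exams`
#' eligible examinations (CKD-EPI eGFR >= 60 by default); see
#' [generative_config()] for the generative model. Subjects whose exams
#' are all ineligible are regenerated; the eligible total is trimmed (last
#' exams of the most-examined subjects dropped) or topped up (sparsest
#' subjects regenerated at the maximum exam count) to land exactly on
#' `total_exams`. Deterministic given `seed`.
#'
#' @param config A [generative_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A [gfr_cohort] with all exams eligible, `agfr`/`mgfr` filled
#'   in, and the latent generative residuals retrievable via
#'   `attr(cohort, "latent")` (data frame with `inv_scr_resid` and
#'   `log_agfr_resid` aligned to rows).
#' @examples
#' coh <- simulate_cohort(generative_config(n_subjects = 30,
#'                                          total_exams = 300), seed = 42)
#' @export
simulate_cohort <- function(config = generative_config(), seed = NULL) {
  stopifnot(inherits(config, "gfr_generative_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  n_sub <- cfg$n_subjects
  ids <- sprintf("S%04d", seq_len(n_sub))
  sexes <- ifelse(stats::runif(n_sub) < cfg$sex_ratio, "female", "male")
  counts <- sample(seq(cfg$exam_count_range[1], cfg$exam_count_range[2]),
                   n_sub, replace = TRUE)
  subs <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    for (att in seq_len(cfg$max_attempts)) {
      d <- simulate_subject(ids[i], sexes[i], counts[i], cfg)
      d <- d[eligible_rows(d, cfg), , drop = FALSE]
      if (nrow(d) > 0) break
      if (att == cfg$max_attempts) {
        stop("unreachable configuration: subject ", ids[i],
             " produced no eligible exams after ", cfg$max_attempts,
             " attempts", call. = FALSE)
      }
    }
    subs[[i]] <- d
  }
  per_n <- vapply(subs, nrow, 0L)
  total <- sum(per_n)
  # top up: regenerate the sparsest subjects at the maximum exam count
  att <- 0
  while (total < cfg$total_exams) {
    att <- att + 1
    if (att > cfg$max_attempts) {
      stop("unreachable configuration: could not reach ", cfg$total_exams,
           " eligible exams", call. = FALSE)
    }
    i <- which.min(per_n)
    d <- simulate_subject(ids[i], sexes[i], cfg$exam_count_range[2], cfg)
    d <- d[eligible_rows(d, cfg), , drop = FALSE]
    if (nrow(d) > per_n[i]) {
      subs[[i]] <- d
      total <- total + nrow(d) - per_n[i]
      per_n[i] <- nrow(d)
    }
  }
  # trim: drop last exams of the most-examined subjects
  while (total > cfg$total_exams) {
    i <- which.max(per_n)
    subs[[i]] <- subs[[i]][-nrow(subs[[i]]), , drop = FALSE]
    per_n[i] <- per_n[i] - 1L
    total <- total - 1L
  }
  df <- do.call(rbind, subs)
  latent <- data.frame(inv_scr_resid = df$.inv_scr_resid,
                       log_agfr_resid = df$.log_agfr_resid)
  df$.inv_scr_resid <- NULL
  df$.log_agfr_resid <- NULL
  df <- resequence_exams(df)
  cohort <- as_gfr_cohort(df)
  attr(cohort, "latent") <- latent
  attr(cohort, "config") <- cfg
  cohort
}

# exam-level reference moments of the emulated cohort (per sex), used by
# calibration_report() for side-by-side comparison
reference_moments <- function() {
  data.frame(
    variable = rep(c("age", "height", "weight", "fpg", "hba1c", "scr",
                     "duration", "agfr", "egfr_ckd_epi", "bsa"), each = 2),
    sex = rep(c("male", "female"), times = 10),
    ref_mean = c(49.4, 48.5, 1.718, 1.606, 99.3, 94.0, 190.9, 214.3,
                 9.0, 9.7, 0.82, 0.65, 12.5, 13.5, 130.5, 130.4,
                 102.6, 105.7, 2.10, 1.96),
    ref_sd = c(10.0, 11.0, 0.059, 0.060, 26.2, 23.4, 77.5, 85.7,
               2.3, 2.2, 0.17, 0.15, 9.5, 8.2, 39.2, 41.0,
               16.3, 18.3, 0.26, 0.22),
    stringsAsFactors = FALSE)
}

#' Per-sex moment summary of a cohort, against reference values
#'
#' Computes exam-level means and standard deviations of the clinical
#' variables (plus derived CKD-EPI eGFR and BSA) separately for men and
#' women, side by side with the reference moments of the cohort the
#' simulator emulates. With fewer than two exams in a sex the sd is `NA`.
#'
#' @param cohort A [gfr_cohort].
#' @return A data frame: `variable`, `sex`, `n`, `mean`, `sd`, `ref_mean`,
#'   `ref_sd`.
#' @export
calibration_report <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  work <- data.frame(
    sex = cohort$sex, age = cohort$age, height = cohort$height,
    weight = cohort$weight, fpg = cohort$fpg, hba1c = cohort$hba1c,
    scr = cohort$scr, duration = cohort$duration, agfr = cohort$agfr,
    egfr_ckd_epi = ckd_epi(cohort$sex, cohort$age, cohort$scr),
    bsa = dubois_bsa(cohort$height, cohort$weight))
  ref <- reference_moments()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    v <- ref$variable[i]; sx <- ref$sex[i]
    x <- work[[v]][work$sex == sx]
    x <- x[!is.na(x)]
    data.frame(variable = v, sex = sx, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               ref_mean = ref$ref_mean[i], ref_sd = ref$ref_sd[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
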