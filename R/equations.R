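#' Du Bois body surface area
#'
#' Computes body surface area from height and weight with the Du Bois &
#' Du Bois power law, `0.007184 * height_cm^0.725 * weight_kg^0.425`.
#' Height is taken in metres (the convention used throughout this package)
#' and converted to centimetres internally.
#'
#' @param height Height in metres. Vectorised.
#' @param weight Weight in kilograms. Vectorised.
#' @return Body surface area in square metres.
#' @examples
#' dubois_bsa(1.718, 99.3) # ~2.12 m^2
#' @export
dubois_bsa <- function(height, weight) {
  if (any(!is.finite(height)) || any(!is.finite(weight)) ||
      any(height <= 0) || any(weight <= 0)) {
    stop("dubois_bsa(): height and weight must be finite and positive",
         call. = FALSE)
  }
  0.007184 * (height * 100)^0.725 * weight^0.425
}

#' Index a measured GFR to 1.73 m^2 of body surface area
#'
#' @param mgfr Measured (e.g. iothalamate-clearance) GFR in mL/min.
#' @param bsa Body surface area in m^2.
#' @return Adjusted GFR (aGFR) in mL/min/1.73m^2, i.e. `mgfr / bsa * 1.73`.
#' @export
adjust_gfr <- function(mgfr, bsa) {
  if (any(!is.finite(mgfr)) || any(mgfr < 0)) {
    stop("adjust_gfr(): mgfr must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(bsa)) || any(bsa <= 0)) {
    stop("adjust_gfr(): bsa must be finite and positive", call. = FALSE)
  }
  mgfr / bsa * 1.73
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("f", "female", "w", "woman", "women")] <- "female"
  s[s %in% c("m", "male", "man", "men")] <- "male"
  bad <- !(s %in% c("male", "female"))
  if (any(bad)) {
    stop("unknown sex code(s): ", paste(unique(sex[bad]), collapse = ", "),
         " (expected male/female or M/F)", call. = FALSE)
  }
  s
}

#' CKD-EPI creatinine eGFR (2009, non-black coefficients)
#'
#' Four-branch creatinine equation with sex-specific knots at 0.7 mg/dL
#' (female) and 0.9 mg/dL (male):
#' \deqn{eGFR = a \times (SCR/k)^{e} \times 0.993^{age}}
#' with a = 144 (female) or 141 (male), k the sex knot, and exponent
#' -0.329 / -0.411 below the knot and -1.209 above it. Only the constants
#' for non-black race are implemented; no race multiplier is exposed.
#'
#' @param sex "male"/"female" (or M/F), recycled against the numeric inputs.
#' @param age Age in years.
#' @param scr Serum creatinine in mg/dL.
#' @return eGFR in mL/min/1.73m^2.
#' @examples
#' ckd_epi("female", 50, 0.7) # 144 * 0.993^50
#' @export
ckd_epi <- function(sex, age, scr) {
  sex <- normalize_sex(sex)
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("ckd_epi(): age must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("ckd_epi(): scr must be finite and positive", call. = FALSE)
  }
  n <- max(length(sex), length(age), length(scr))
  sex <- rep_len(sex, n); age <- rep_len(age, n); scr <- rep_len(scr, n)
  female <- sex == "female"
  a <- ifelse(female, 144, 141)
  k <- ifelse(female, 0.7, 0.9)
  lo <- ifelse(female, -0.329, -0.411)
  ex <- ifelse(scr <= k, lo, -1.209)
  a * (scr / k)^ex * 0.993^age
}

#' MDRD study eGFR (IDMS-traceable, non-black coefficients)
#'
#' \deqn{eGFR = 175 \times SCR^{-1.154} \times age^{-0.203} [\times 0.742
#' \text{ if female}]}
#'
#' @inheritParams ckd_epi
#' @return eGFR in mL/min/1.73m^2.
#' @export
mdrd <- function(sex, age, scr) {
  sex <- normalize_sex(sex)
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("mdrd(): age must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("mdrd(): scr must be finite and positive", call. = FALSE)
  }
  n <- max(length(sex), length(age), length(scr))
  sex <- rep_len(sex, n); age <- rep_len(age, n); scr <- rep_len(scr, n)
  175 * scr^-1.154 * age^-0.203 * ifelse(sex == "female", 0.742, 1)
}

#' Hyperfiltration classification rule
#'
#' Hyperfiltration is abnormally high glomerular filtration, a putative
#' early marker of diabetic kidney injury. The conventional working
#' definition is aGFR above 120 mL/min/1.73m^2; whether the boundary itself
#' counts is reported inconsistently in the literature, so the comparison
#' mode is configurable (default: strictly greater).
#'
#' @param threshold Positive threshold in mL/min/1.73m^2 (default 120).
#' @param comparison `"gt"` (strictly greater, default) or `"ge"`.
#' @return An object of class `hyperfiltration_rule`.
#' @export
hyperfiltration_rule <- function(threshold = 120, comparison = c("gt", "ge")) {
  comparison <- match.arg(comparison)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  structure(list(threshold = threshold, comparison = comparison),
            class = "hyperfiltration_rule")
}

#' Classify hyperfiltration from measured aGFR
#'
#' @param agfr Adjusted GFR values (mL/min/1.73m^2), non-negative.
#' @param rule A [hyperfiltration_rule()].
#' @return Logical vector.
#' @export
classify_hyperfiltration <- function(agfr, rule = hyperfiltration_rule()) {
  stopifnot(inherits(rule, "hyperfiltration_rule"))
  if (any(!is.finite(agfr)) || any(agfr < 0)) {
    stop("classify_hyperfiltration(): agfr must be finite and non-negative",
         call. = FALSE)
  }
  if (rule$comparison == "gt") agfr > rule$threshold else agfr >= rule$threshold
}
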