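#' Stratified log-linear GFR approximating equations
#'
#' An equation spec is a set of per-stratum log-linear equations. Strata are
#' defined by sex and half-open serum-creatinine intervals `[lo, hi)` that
#' partition the positive reals for each sex (bottom stratum `(0, hi)`, top
#' `[lo, Inf)`). Within a stratum the prediction is
#' \deqn{\widehat{aGFR} = \exp\big(b_0 + \sum_v b_v \, x_v / s_v\big)}
#' where `s_v` is a per-variable scaling divisor recorded in the spec (e.g.
#' age in decades, FPG per 100 mg/dL).
#'
#' @param name Spec name.
#' @param strata Data frame with columns `sex`, `scr_lo`, `scr_hi`,
#'   `intercept`, plus one column per covariate coefficient (e.g. `age`,
#'   `hba1c`, `fpg`, `scr`).
#' @param scaling Named numeric vector of divisors, one entry per
#'   coefficient column (a divisor of 1 means the raw unit is used).
#' @return An object of class `gfr_equation_spec`.
#' @seealso [pima_equations()], [predict_equation()], [stratum_for()]
#' @export
equation_spec <- function(name, strata, scaling) {
  stopifnot(is.data.frame(strata))
  fixed <- c("sex", "scr_lo", "scr_hi", "intercept")
  if (!all(fixed %in% names(strata))) {
    stop("strata must have columns ", paste(fixed, collapse = ", "),
         call. = FALSE)
  }
  vars <- setdiff(names(strata), fixed)
  if (length(vars) == 0) stop("spec has no coefficient columns", call. = FALSE)
  if (!is.numeric(scaling) || is.null(names(scaling)) ||
      !setequal(names(scaling), vars)) {
    stop("scaling must be a named numeric vector covering exactly: ",
         paste(vars, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(scaling)) || any(scaling == 0)) {
    stop("scaling divisors must be finite and non-zero", call. = FALSE)
  }
  strata$sex <- normalize_sex(strata$sex)
  strata <- strata[order(strata$sex, strata$scr_lo), , drop = FALSE]
  rownames(strata) <- NULL
  spec <- structure(list(name = as.character(name), link = "log",
                         strata = strata, variables = vars,
                         scaling = scaling[vars]),
                    class = "gfr_equation_spec")
  validate_equation_spec(spec)
  spec
}

#' Validate an equation spec's stratum partition
#'
#' Checks that, for each sex present, the serum-creatinine intervals tile
#' `(0, Inf)` with no gap and no overlap.
#'
#' @param spec A `gfr_equation_spec`.
#' @return `spec`, invisibly; errors on violation.
#' @export
validate_equation_spec <- function(spec) {
  stopifnot(inherits(spec, "gfr_equation_spec"))
  st <- spec$strata
  for (sx in unique(st$sex)) {
    s <- st[st$sex == sx, , drop = FALSE]
    s <- s[order(s$scr_lo), , drop = FALSE]
    if (any(s$scr_hi <= s$scr_lo)) {
      stop("spec '", spec$name, "': empty interval for sex ", sx,
           call. = FALSE)
    }
    if (s$scr_lo[1] != 0) {
      stop("spec '", spec$name, "': bottom stratum for sex ", sx,
           " must start at 0", call. = FALSE)
    }
    if (is.finite(s$scr_hi[nrow(s)])) {
      stop("spec '", spec$name, "': top stratum for sex ", sx,
           " must be unbounded", call. = FALSE)
    }
    if (nrow(s) > 1) {
      lo <- s$scr_lo[-1]; hi <- s$scr_hi[-nrow(s)]
      if (any(lo != hi)) {
        k <- which(lo != hi)[1]
        stop("spec '", spec$name, "': strata for sex ", sx,
             if (lo[k] > hi[k]) " have a gap at " else " overlap at ",
             format(min(lo[k], hi[k])), call. = FALSE)
      }
    }
  }
  invisible(spec)
}

#' Locate the stratum matching an examination
#'
#' @param spec A `gfr_equation_spec`.
#' @param sex,scr Sex code(s) and serum creatinine (mg/dL); vectorised.
#' @return Integer row indices into `spec$strata`.
#' @export
stratum_for <- function(spec, sex, scr) {
  stopifnot(inherits(spec, "gfr_equation_spec"))
  sex <- normalize_sex(sex)
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("stratum_for(): scr must be finite and positive", call. = FALSE)
  }
  n <- max(length(sex), length(scr))
  sex <- rep_len(sex, n); scr <- rep_len(scr, n)
  st <- spec$strata
  idx <- integer(n)
  for (i in seq_len(n)) {
    hit <- which(st$sex == sex[i] & scr[i] >= st$scr_lo & scr[i] < st$scr_hi)
    if (length(hit) != 1) {
      stop("no stratum for sex ", sex[i], ", scr ", scr[i], call. = FALSE)
    }
    idx[i] <- hit
  }
  idx
}

#' Predict approximated GFR from a stratified equation spec
#'
#' Evaluates, per examination, the stratum-specific linear predictor on the
#' spec's scaled covariates and applies the log link.
#'
#' @param spec A `gfr_equation_spec`.
#' @param exams A [gfr_cohort] or data frame carrying `sex`, `scr` and every
#'   covariate the spec uses (`age`, `fpg`, `hba1c`, ...).
#' @return Numeric vector of approximated GFR (mL/min/1.73m^2), positive.
#' @export
predict_equation <- function(spec, exams) {
  stopifnot(inherits(spec, "gfr_equation_spec"), is.data.frame(exams))
  need <- unique(c("sex", "scr", spec$variables))
  missing_cols <- setdiff(need, names(exams))
  if (length(missing_cols)) {
    stop("exams lack covariate(s) required by spec '", spec$name, "': ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (v in spec$variables) {
    if (anyNA(exams[[v]])) {
      stop("missing values in covariate '", v, "' required by spec '",
           spec$name, "'", call. = FALSE)
    }
  }
  idx <- stratum_for(spec, exams$sex, exams$scr)
  st <- spec$strata
  x <- st$intercept[idx]
  for (v in spec$variables) {
    x <- x + st[[v]][idx] * exams[[v]] / spec$scaling[[v]]
  }
  exp(x)
}

#' @export
print.gfr_equation_spec <- function(x, ...) {
  cat(sprintf("<gfr_equation_spec> '%s': %d strata, link = %s\n",
              x$name, nrow(x$strata), x$link))
  cat("scaling divisors: ",
      paste(sprintf("%s/%g", names(x$scaling), x$scaling), collapse = ", "),
      "\n", sep = "")
  print(x$strata, ...)
  invisible(x)
}

#' The published Pima glycemia-aware approximating equations
#'
#' Returns the shipped eight-stratum equation spec (four serum-creatinine
#' strata per sex) for approximating aGFR from age, HbA1c, FPG and SCR in
#' adults with type 2 diabetes.
#'
#' Two caveats are inherited from the printed source of these coefficients:
#' the variable scalings were not stated alongside the coefficients, and
#' the defaults used here (age in decades, FPG per 100 mg/dL, HbA1c and SCR
#' in raw units) are an inference from the companion regression models, not
#' a published statement — predictions from this spec should be treated as
#' provisional, with re-derivation via [cross_validate()] as the canonical
#' route. Two typographic anomalies in the printed table are corrected: the
#' men's top-stratum HbA1c coefficient "00.328" is encoded as 0.0328, and
#' its lower bound "-0.90" as 0.90 mg/dL.
#'
#' @return A `gfr_equation_spec` with 8 strata.
#' @export
pima_equations <- function() {
  path <- system.file("extdata", "pima_equations.tsv", package = "glycogfr",
                      mustWork = TRUE)
  read_equation_spec(path)
}

#' Serialize / deserialize an equation spec
#'
#' The on-disk format is a small text file: `key: value` header lines
#' (`name`, `link`, `scaling`) followed by a tab-separated stratum table.
#' Numbers are written with 17 significant digits so that a write/read
#' round trip is bit-exact.
#'
#' @param spec A `gfr_equation_spec`.
#' @param path File path.
#' @return `read_equation_spec` returns the spec; `write_equation_spec`
#'   returns `path` invisibly.
#' @export
write_equation_spec <- function(spec, path) {
  stopifnot(inherits(spec, "gfr_equation_spec"))
  num <- function(x) sprintf("%.17g", x)
  hdr <- c(paste0("name: ", spec$name),
           paste0("link: ", spec$link),
           paste0("scaling: ",
                  paste(sprintf("%s=%s", names(spec$scaling),
                                num(spec$scaling)), collapse = ", ")))
  st <- spec$strata
  cols <- c("sex", "scr_lo", "scr_hi", "intercept", spec$variables)
  tab <- vapply(seq_len(nrow(st)), function(i) {
    paste(c(st$sex[i], num(st$scr_lo[i]), num(st$scr_hi[i]),
            num(st$intercept[i]),
            vapply(spec$variables, function(v) num(st[[v]][i]), "")),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, paste(cols, collapse = "\t"), tab), path)
  invisible(path)
}

#' @rdname write_equation_spec
#' @export
read_equation_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- grep("^[a-z]+:", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^", key, ":"), kv, value = TRUE)
    if (length(hit) != 1) stop("spec file lacks '", key, ":' header",
                               call. = FALSE)
    trimws(sub(paste0("^", key, ":"), "", hit))
  }
  name <- get("name"); link <- get("link")
  if (link != "log") stop("unsupported link: ", link, call. = FALSE)
  sc_parts <- strsplit(strsplit(get("scaling"), ",")[[1]], "=")
  scaling <- vapply(sc_parts, function(p) as.numeric(trimws(p[2])), 0)
  names(scaling) <- vapply(sc_parts, function(p) trimws(p[1]), "")
  tab_lines <- lines[!grepl("^[a-z]+:", lines)]
  con <- textConnection(tab_lines)
  on.exit(close(con))
  st <- utils::read.delim(con, stringsAsFactors = FALSE)
  if (any(st$scr_hi == "Inf")) st$scr_hi <- as.numeric(st$scr_hi)
  equation_spec(name, st, scaling)
}
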