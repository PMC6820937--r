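#' @title Longitudinal GFR cohorts
#' @description A cohort is a data frame with one row per GFR study
#' (examination), grouped by subject and ordered by `exam_index` within
#' subject. Required columns: `subject_id`, `exam_index` (1-based ordinal
#' within subject), `age` (years), `sex` ("male"/"female"), `height` (m),
#' `weight` (kg), `scr` (serum creatinine, mg/dL), `fpg` (fasting plasma
#' glucose, mg/dL), `hba1c` (%). Optional: `duration` (diabetes duration,
#' years), `mgfr` (measured GFR, mL/min), `agfr` (mgfr indexed to
#' 1.73 m^2). Missing optional values are `NA`.
#' @name gfr_cohort
NULL

COHORT_COLS <- c("subject_id", "exam_index", "age", "sex", "height",
                 "weight", "scr", "fpg", "hba1c", "duration", "mgfr", "agfr")

# CSV header (external interchange schema) -> internal names
CSV_SCHEMA <- c(subject_id = "subject_id", exam_index = "exam_index",
                age_years = "age", sex = "sex", height_m = "height",
                weight_kg = "weight", scr_mg_dl = "scr", fpg_mg_dl = "fpg",
                hba1c_pct = "hba1c", duration_years = "duration",
                mgfr_ml_min = "mgfr", agfr_ml_min_1p73 = "agfr")

#' Construct and validate a GFR cohort
#'
#' @param df Data frame carrying the columns documented in [gfr_cohort].
#'   Optional columns absent from `df` are added as `NA`.
#' @return A validated `gfr_cohort` data frame sorted by
#'   (`subject_id`, `exam_index`).
#' @export
as_gfr_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  req <- setdiff(COHORT_COLS, c("duration", "mgfr", "agfr"))
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (opt in c("duration", "mgfr", "agfr")) {
    if (is.null(df[[opt]])) df[[opt]] <- NA_real_
  }
  df <- as.data.frame(df)[, COHORT_COLS]
  df$subject_id <- as.character(df$subject_id)
  df$sex <- normalize_sex(df$sex)
  bad <- validate_exam_rows(df)
  if (length(bad)) {
    stop("invalid examination row(s): ",
         paste(sprintf("row %d (%s)", as.integer(names(bad)),
                       unlist(bad)), collapse = "; "),
         call. = FALSE)
  }
  df <- df[order(df$subject_id, df$exam_index), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gfr_cohort", "data.frame")
  df
}

# Returns a named list: names are row numbers, values the violated rule.
validate_exam_rows <- function(df) {
  msg <- character(nrow(df))
  chk <- function(ok, label) {
    viol <- !ok & !nzchar(msg)
    msg[viol] <<- label
  }
  fin_pos <- function(x) is.finite(x) & x > 0
  chk(fin_pos(df$age), "age must be > 0")
  chk(fin_pos(df$scr), "scr must be > 0")
  chk(fin_pos(df$height), "height must be > 0")
  chk(fin_pos(df$weight), "weight must be > 0")
  chk(fin_pos(df$fpg), "fpg must be > 0")
  chk(is.finite(df$hba1c) & df$hba1c > 0 & df$hba1c < 25,
      "hba1c must be in (0, 25)")
  chk(is.na(df$duration) | (is.finite(df$duration) & df$duration >= 0),
      "duration must be >= 0 when present")
  chk(is.na(df$mgfr) | (is.finite(df$mgfr) & df$mgfr >= 0),
      "mgfr must be >= 0 when present")
  chk(is.na(df$agfr) | fin_pos(df$agfr), "agfr must be > 0 when present")
  idx <- which(nzchar(msg))
  stats::setNames(as.list(msg[idx]), idx)
}

resequence_exams <- function(df) {
  df <- df[order(df$subject_id, df$exam_index), , drop = FALSE]
  df$exam_index <- stats::ave(seq_len(nrow(df)), df$subject_id,
                              FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' Restrict a cohort to eligible examinations
#'
#' Hyperfiltration, by definition, does not occur in established chronic
#' kidney disease, so examinations with an estimated GFR below 60
#' mL/min/1.73m^2 are removed before derivation and evaluation. The
#' criterion is the CKD-EPI eGFR by default; measured aGFR may be used
#' instead as a sensitivity variant.
#'
#' @param cohort A [gfr_cohort].
#' @param mode `"ckd_epi_egfr"` (default) or `"agfr"`.
#' @param threshold Eligibility bound; exams with criterion value
#'   `>= threshold` are retained (default 60).
#' @return The filtered cohort, with `exam_index` re-sequenced per subject
#'   (subject grouping and within-subject order preserved).
#' @export
filter_eligible <- function(cohort, mode = c("ckd_epi_egfr", "agfr"),
                            threshold = 60) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(cohort))
  crit <- if (mode == "ckd_epi_egfr") {
    ckd_epi(cohort$sex, cohort$age, cohort$scr)
  } else {
    if (anyNA(cohort$agfr)) {
      bad <- which(is.na(cohort$agfr))
      stop("filter_eligible(mode = \"agfr\"): agfr missing for exam(s) ",
           paste(utils::head(paste0(cohort$subject_id[bad], "/",
                                    cohort$exam_index[bad]), 5),
                 collapse = ", "), call. = FALSE)
    }
    cohort$agfr
  }
  out <- cohort[crit >= threshold, , drop = FALSE]
  out <- resequence_exams(out)
  class(out) <- c("gfr_cohort", "data.frame")
  out
}

#' Read a cohort from CSV
#'
#' Expects the documented interchange schema (comma-separated, UTF-8,
#' header row): `subject_id, exam_index, age_years, sex, height_m,
#' weight_kg, scr_mg_dl, fpg_mg_dl, hba1c_pct, duration_years,
#' mgfr_ml_min, agfr_ml_min_1p73`. Sex is M/F (case-insensitive); an empty
#' cell is a missing value.
#'
#' @param path CSV file path.
#' @param strict If `TRUE` (default), any invalid row aborts the load with
#'   line-numbered messages; otherwise invalid rows are dropped with a
#'   warning.
#' @return A [gfr_cohort].
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  missing_cols <- setdiff(names(CSV_SCHEMA), names(raw))
  if (length(missing_cols)) {
    stop("malformed cohort header; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) stop("cohort file has no data rows: ", path,
                           call. = FALSE)
  df <- raw[, names(CSV_SCHEMA)]
  names(df) <- unname(CSV_SCHEMA)
  df$sex <- normalize_sex(df$sex)
  bad <- validate_exam_rows(df)
  if (length(bad)) {
    # +1 header line to report file line numbers
    msgs <- sprintf("line %d: %s", as.integer(names(bad)) + 1L, unlist(bad))
    if (strict) {
      stop("invalid cohort rows:\n  ", paste(msgs, collapse = "\n  "),
           call. = FALSE)
    }
    warning("dropping invalid cohort rows:\n  ",
            paste(msgs, collapse = "\n  "), call. = FALSE)
    df <- df[-as.integer(names(bad)), , drop = FALSE]
    if (nrow(df) == 0) stop("no valid rows remain in ", path, call. = FALSE)
  }
  as_gfr_cohort(df)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]; numeric values are written at full precision
#' so that a write/read round trip reproduces the cohort exactly.
#'
#' @param cohort A [gfr_cohort].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  out <- as.data.frame(cohort)[, COHORT_COLS]
  names(out) <- names(CSV_SCHEMA)
  out$sex <- ifelse(out$sex == "female", "F", "M")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.gfr_cohort <- function(x, ...) {
  cat(sprintf("<gfr_cohort> %d examinations, %d subjects (%d women, %d men)\n",
              nrow(x), length(unique(x$subject_id)),
              sum(x$sex == "female"), sum(x$sex == "male")))
  NextMethod()
}
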