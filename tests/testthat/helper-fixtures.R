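# Shared fixtures, built in code. Heavier simulated cohorts are cached per
# test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# a small but realistic simulated cohort (fast to generate)
small_cohort <- function(seed = 101) {
  cached(paste0("small", seed), {
    cfg <- generative_config(n_subjects = 60, total_exams = 600)
    simulate_cohort(cfg, seed = seed)
  })
}

# the full-size default cohort (shared by calibration-style tests)
default_cohort <- function(seed = 1) {
  cached(paste0("default", seed), simulate_cohort(generative_config(),
                                                  seed = seed))
}

# hand-built deterministic mini cohort (no RNG): 3 subjects x 3 exams
toy_cohort <- function() {
  df <- expand.grid(exam_index = 1:3, subject_id = c("A", "B", "C"),
                    stringsAsFactors = FALSE)
  df$sex <- rep(c("female", "male", "female"), each = 3)
  df$age <- 40 + df$exam_index * 2 + (match(df$subject_id, c("A", "B", "C")) - 1) * 5
  df$height <- rep(c(1.60, 1.75, 1.65), each = 3)
  df$weight <- rep(c(90, 100, 85), each = 3) + df$exam_index
  df$scr <- rep(c(0.6, 0.8, 0.7), each = 3) + 0.02 * df$exam_index
  df$fpg <- rep(c(210, 180, 230), each = 3) + 5 * df$exam_index
  df$hba1c <- rep(c(9.5, 8.5, 10.2), each = 3)
  df$duration <- 5 + df$exam_index
  df$agfr <- rep(c(135, 128, 122), each = 3) - 2 * df$exam_index
  df$mgfr <- df$agfr * dubois_bsa(df$height, df$weight) / 1.73
  as_gfr_cohort(df)
}

# single-stratum spec with given intercept/coefficients (degenerate default)
flat_spec <- function(intercept = 4.8, coefs = c(age = 0, hba1c = 0,
                                                 fpg = 0, scr = 0)) {
  st <- data.frame(sex = c("female", "male"), scr_lo = 0, scr_hi = Inf,
                   intercept = intercept)
  for (v in names(coefs)) st[[v]] <- coefs[[v]]
  equation_spec("flat", st, c(age = 10, hba1c = 1, fpg = 100, scr = 1))
}
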