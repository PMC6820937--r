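test_that("quartile cut points follow the type-7 rule and reference layout", {
  df <- toy_cohort()[1:8, ]
  df$subject_id <- letters[1:8]; df$exam_index <- 1L
  df$sex <- "female"; df$scr <- 1:8
  cuts <- scr_quartile_cutpoints(as_gfr_cohort(df))
  expect_equal(cuts$female, c(2.75, 4.5, 6.25))
  # cut points partition the 8 exams 2/2/2/2
  strata <- cut(df$scr, c(0, cuts$female, Inf), right = FALSE)
  expect_equal(as.vector(table(strata)), c(2, 2, 2, 2))
  # a sex absent from the cohort is an error
  expect_error(scr_quartile_cutpoints(as_gfr_cohort(df),
                                      sexes = c("female", "male")),
               "no examinations")
  # default cohort: women's cut points near the reference stratum bounds
  cuts_def <- scr_quartile_cutpoints(default_cohort())
  expect_equal(cuts_def$female, c(0.55, 0.62, 0.72), tolerance = 0.1)
})

test_that("degenerate (constant) SCR collapses to one stratum with warning", {
  coh <- small_cohort()
  coh <- coh[coh$sex == "female", ]   # one sex -> exactly one warning
  coh$scr <- 0.7
  cuts <- scr_quartile_cutpoints(coh)
  expect_warning(spec <- fit_stratified_equations(coh, cuts), "degenerate")
  expect_equal(nrow(spec$strata), 1)
})

test_that("stratified fit recovers structure and beats CKD-EPI on its cohort", {
  coh <- default_cohort()
  cuts <- scr_quartile_cutpoints(coh)
  spec <- fit_stratified_equations(coh, cuts)
  expect_equal(nrow(spec$strata), 8)
  expect_equal(spec$variables, c("age", "hba1c", "fpg", "scr"))
  pred <- predict_equation(spec, coh)
  r_new <- cor(pred, coh$agfr)
  r_ckd <- cor(ckd_epi(coh$sex, coh$age, coh$scr), coh$agfr)
  expect_gt(r_new, r_ckd)
  # under-filled stratum is a named error
  tiny <- coh[1:12, ]
  expect_error(fit_stratified_equations(tiny, cuts), "too few exams")
})

test_that("glycemia-null strata yield glycemia coefficients within noise", {
  # clustered covariates and AR(1) residuals make single-cohort stratum
  # coefficients noisy; average them over seeds to isolate systematic bias
  cfg <- inject_known_effects(
    generative_config(n_subjects = 150, total_exams = 1500),
    c(agfr_model.fpg10 = 0, agfr_model.hba1c = 0))
  acc <- replicate(5, NULL, simplify = FALSE)
  for (s in 1:5) {
    coh <- simulate_cohort(cfg, seed = 16 + s)
    spec <- fit_stratified_equations(coh, scr_quartile_cutpoints(coh))
    acc[[s]] <- as.matrix(spec$strata[, c("fpg", "hba1c")])
  }
  mean_coef <- Reduce(`+`, acc) / length(acc)
  # coefficients on the scaled variables: fpg is per 100 mg/dL here
  expect_lt(max(abs(mean_coef[, "fpg"])), 0.07)
  expect_lt(max(abs(mean_coef[, "hba1c"])), 0.03)
})

test_that("fold assignment is balanced, seeded and subject-level", {
  coh <- default_cohort()
  folds <- assign_folds(coh, k = 10, seed = 99)
  sizes <- as.vector(table(folds))
  expect_equal(sort(sizes), sort(c(rep(27, 9), 26)))
  expect_equal(length(folds), 269)
  expect_identical(folds, assign_folds(coh, k = 10, seed = 99))
  expect_false(identical(folds, assign_folds(coh, k = 10, seed = 100)))
  # every exam inherits its subject's fold: mapping is well defined
  exam_folds <- folds[coh$subject_id]
  expect_equal(as.vector(tapply(exam_folds, coh$subject_id,
                                function(f) length(unique(f)))),
               rep(1, 269))
  expect_error(assign_folds(coh, k = 300, seed = 1), "exceeds")
  expect_error(assign_folds(coh, k = 10), "seed")
})

test_that("cross-validation is leakage-free and averages fold coefficients", {
  coh <- small_cohort()
  cv <- cross_validate(coh, k = 5, seed = 42)
  # exactly one out-of-fold prediction per exam
  expect_true(all(is.finite(cv$oof_predictions)))
  expect_equal(length(cv$oof_predictions), nrow(coh))
  # audit: rebuild each fold's training set; held-out subjects disjoint
  exam_fold <- cv$folds[coh$subject_id]
  for (f in seq_len(cv$k)) {
    train_subj <- unique(coh$subject_id[exam_fold != f])
    test_subj <- unique(coh$subject_id[exam_fold == f])
    expect_length(intersect(train_subj, test_subj), 0)
  }
  # held-out predictions reproduce the fold spec applied to held-out exams
  f1 <- which(exam_fold == 1)
  expect_equal(cv$oof_predictions[f1],
               predict_equation(cv$fold_specs[[1]], coh[f1, ]))
  # final spec is the stratum-wise arithmetic mean of the fold specs
  for (col in c("scr_lo", "scr_hi", "intercept", "age", "hba1c", "fpg",
                "scr")) {
    mean_col <- rowMeans(sapply(cv$fold_specs,
                                function(s) s$strata[[col]]))
    expect_equal(cv$final_spec$strata[[col]], mean_col)
  }
})

test_that("out-of-fold fit is not optimistic relative to in-sample fit", {
  r_in <- r_out <- numeric(3)
  for (i in 1:3) {
    coh <- simulate_cohort(generative_config(n_subjects = 80,
                                             total_exams = 800),
                           seed = 300 + i)
    cv <- cross_validate(coh, k = 5, seed = i)
    spec_full <- fit_stratified_equations(coh, scr_quartile_cutpoints(coh))
    r_in[i] <- cor(predict_equation(spec_full, coh), coh$agfr)^2
    r_out[i] <- cor(cv$oof_predictions, coh$agfr)^2
  }
  expect_lt(mean(r_out), mean(r_in))
})
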