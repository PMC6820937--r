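test_that("simulation is deterministic given a seed and hits the design counts", {
  cfg <- generative_config(n_subjects = 40, total_exams = 400)
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "latent"), attr(b, "latent"))
  c2 <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))

  expect_equal(nrow(a), 400)
  expect_equal(length(unique(a$subject_id)), 40)
  # every exam passes the eligibility screen by construction
  expect_true(all(ckd_epi(a$sex, a$age, a$scr) >= 60))
  # ages strictly increase within subject
  expect_true(all(unlist(tapply(a$age, a$subject_id, diff)) > 0))
  # latent residuals are retrievable and aligned
  expect_equal(nrow(attr(a, "latent")), nrow(a))
  expect_true(all(c("inv_scr_resid", "log_agfr_resid") %in%
                  names(attr(a, "latent"))))
})

test_that("default cohort matches the directly parameterised moments", {
  coh <- default_cohort()
  expect_equal(nrow(coh), 2798)
  expect_equal(length(unique(coh$subject_id)), 269)
  cr <- calibration_report(coh)
  get <- function(v, s, col) cr[[col]][cr$variable == v & cr$sex == s]
  # covariate moments are sampled directly: tight agreement
  for (v in c("fpg", "hba1c", "height", "weight")) {
    for (s in c("male", "female")) {
      # means of the rarer sex carry cluster-level sampling error
      # (~80 male subjects): allow ~2.5 cluster SEs
      expect_equal(get(v, s, "mean"), get(v, s, "ref_mean"),
                   tolerance = 0.08)
      expect_equal(get(v, s, "sd"), get(v, s, "ref_sd"), tolerance = 0.2)
    }
  }
  # exam-level ages are centred near the reference values
  expect_equal(get("age", "male", "mean"), 49.4, tolerance = 0.04)
  expect_equal(get("age", "female", "mean"), 48.5, tolerance = 0.04)
  # SCR emerges from the generative 1/SCR regression: looser agreement
  expect_equal(get("scr", "female", "mean"), 0.65, tolerance = 0.08)
  expect_equal(get("scr", "male", "mean"), 0.82, tolerance = 0.08)
  # women's share of examinations
  expect_equal(mean(coh$sex == "female"), 1948 / 2798, tolerance = 0.08)
  # glycemia correlation near its copula target
  expect_equal(cor(coh$fpg, coh$hba1c), 0.71, tolerance = 0.03)
})

test_that("inter-exam gaps average near the design mean", {
  coh <- default_cohort()
  gaps <- unlist(tapply(coh$age, coh$subject_id, function(a) diff(sort(a))))
  expect_equal(mean(gaps), 3.3, tolerance = 0.1)  # relative: +/- 0.33 y
})

test_that("injected null glycemia effects remove the aGFR association", {
  cfg <- inject_known_effects(
    generative_config(n_subjects = 120, total_exams = 1200),
    c(agfr_model.fpg10 = 0, agfr_model.hba1c = 0))
  expect_equal(unname(cfg$agfr_model[["fpg10"]]), 0)
  coh <- simulate_cohort(cfg, seed = 3)
  fit <- fit_lmm_ar1(coh, "log_agfr", c("age", "sex", "scr", "fpg10",
                                        "hba1c"))
  est <- fit$coefficients
  for (term in c("fpg10", "hba1c")) {
    i <- which(est$term == term)
    expect_lt(abs(est$estimate[i]), 3 * est$se[i])
  }
})

test_that("injected ar1_rho = 0 yields uncorrelated within-subject residuals", {
  cfg <- inject_known_effects(
    generative_config(n_subjects = 150, total_exams = 1500),
    c(ar1_rho = 0))
  coh <- simulate_cohort(cfg, seed = 5)
  lat <- attr(coh, "latent")$log_agfr_resid
  lag_pairs <- do.call(rbind, tapply(seq_along(lat), coh$subject_id,
    function(ix) if (length(ix) > 1) cbind(lat[ix[-length(ix)]],
                                           lat[ix[-1]])))
  expect_lt(abs(cor(lag_pairs[, 1], lag_pairs[, 2])), 0.06)
  # and with the default rho the lag-1 correlation is clearly positive
  lat2 <- attr(default_cohort(), "latent")$log_agfr_resid
  coh2 <- default_cohort()
  lp2 <- do.call(rbind, tapply(seq_along(lat2), coh2$subject_id,
    function(ix) if (length(ix) > 1) cbind(lat2[ix[-length(ix)]],
                                           lat2[ix[-1]])))
  expect_gt(cor(lp2[, 1], lp2[, 2]), 0.4)
})

test_that("unknown override names and unreachable configs raise errors", {
  expect_error(inject_known_effects(generative_config(),
                                    c(agfr_model.nope = 1)),
               "unknown generative coefficient")
  expect_error(inject_known_effects(generative_config(), c(zzz = 1)),
               "unknown generative parameter")
  expect_error(inject_known_effects(generative_config(), 1),
               "named")
  # an impossible eligibility threshold exhausts regeneration attempts
  cfg <- generative_config(n_subjects = 3, total_exams = 30,
                           eligibility_threshold = 1e6, max_attempts = 3)
  expect_error(simulate_cohort(cfg, seed = 1), "unreachable")
})

test_that("calibration report flags degenerate single-exam cohorts", {
  one <- toy_cohort()[1, ]
  rep1 <- calibration_report(as_gfr_cohort(one))
  expect_true(all(is.na(rep1$sd[rep1$sex == "female" & rep1$n == 1])))
  expect_true(all(rep1$n[rep1$sex == "male"] == 0))
})
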