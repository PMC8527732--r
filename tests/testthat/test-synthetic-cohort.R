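test_that("marginal means and SDs converge to the group parameters", {
  # 10,000 control eyes; sample mean within 2 SE of the published 0.072
  ch <- generate_cohort(cohort_spec(
    n_subjects = c(control = 10000, dr_normal = 1, dr_decreased = 1),
    prob_both_eyes = 0, seed = 42))
  ctrl <- ch$records[ch$records$group == "control", ]
  se <- 0.005 / sqrt(nrow(ctrl))
  expect_lt(abs(mean(ctrl$vd_drcp) - 0.072), 2 * se)
  expect_lt(abs(sd(ctrl$vd_drcp) - 0.005) / 0.005, 0.05)
  expect_lt(abs(mean(ctrl$gcl_ipl_um) - 72.40), 2 * 5.59 / sqrt(nrow(ctrl)))
})

test_that("noiseless degenerate cohort has constant BCVA at the intercept", {
  ch <- generate_cohort(cohort_spec(
    n_subjects = c(control = 5, dr_normal = 5, dr_decreased = 5),
    bcva_coefficients = c(intercept = 0.3, age = 0, vd_drcp = 0,
                          gcl_ipl_um = 0),
    interaction_coefficient = 0, residual_sd = 0, seed = 1))
  expect_equal(ch$records$bcva_logmar, rep(0.3, nrow(ch$records)))
})

test_that("empirical intraclass correlation matches the closed form", {
  lambda <- sqrt(0.5)
  ch <- generate_cohort(cohort_spec(
    n_subjects = c(control = 5000, dr_normal = 1, dr_decreased = 1),
    prob_both_eyes = 1, subject_effect_sd = lambda, seed = 9))
  ctrl <- ch$records[ch$records$group == "control", ]
  od <- ctrl[ctrl$eye == "OD", ]
  os <- ctrl[ctrl$eye == "OS", ]
  os <- os[match(od$subject_id, os$subject_id), ]
  icc_emp <- cor(od$gcl_ipl_um, os$gcl_ipl_um)
  # closed form: subject-share variance over total variance
  expect_lt(abs(icc_emp - lambda^2), 0.02)
})

test_that("cohort structure and invariants hold", {
  rec <- quick_cohort(seed = 3)
  expect_true(all(octaphen:::cohort_columns() %in% names(rec)))
  expect_true(all(is.finite(rec$bcva_logmar)))
  expect_true(all(rec$eye %in% c("OD", "OS")))
  # eyes of one subject share the subject id and appear at most twice
  expect_true(all(table(rec$subject_id) <= 2))
  # two-eye subjects share their participant-level draws
  two <- names(which(table(rec$subject_id) == 2))
  pair <- rec[rec$subject_id == two[1], ]
  expect_equal(pair$age[1], pair$age[2])
  expect_error(generate_cohort(cohort_spec(
    n_subjects = c(control = 0, dr_normal = 5, dr_decreased = 5))),
    "positive")
})

test_that("BCVA follows the published linear predictor", {
  # with no noise anywhere, BCVA is an exact linear function
  ch <- generate_cohort(cohort_spec(
    n_subjects = c(control = 50, dr_normal = 50, dr_decreased = 50),
    residual_sd = 0, seed = 4))
  r <- ch$records
  lp <- 0.575 + 0.002 * r$age - 6.194 * r$vd_drcp - 0.004 * r$gcl_ipl_um
  expect_equal(r$bcva_logmar, lp, tolerance = 1e-12)
})
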