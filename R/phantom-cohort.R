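# Synthetic eye-level cohorts: healthy controls plus two diabetic
# retinopathy groups (normal / decreased visual acuity), with eye-within-
# patient correlation and a known linear model generating BCVA.
#
# Per imaging parameter p with group mean m_p and SD s_p, an eye's value is
#   m_p + s_p * (lambda * z_subject + sqrt(1 - lambda^2) * z_eye)
# where z_subject is shared by both eyes of a participant. The marginal SD
# is s_p and the intraclass correlation is lambda^2. Age and diabetes
# duration are participant-level draws. BCVA (logMAR) is generated from a
# linear predictor in age, DRCP vessel density and GCL-IPL thickness, with
# an optional centered interaction term, plus eye-level residual noise.

cohort_param_names <- function() {
  c("vd_srcp", "vd_drcp", "faz_area_mm2", "rnfl_um", "gcl_ipl_um",
    "inl_um", "opl_um", "total_um")
}

cohort_group_names <- function() c("control", "dr_normal", "dr_decreased")

default_group_means <- function() {
  m <- cbind(
    control      = c(0.056, 0.072, 0.325, 28.46, 72.40, 17.52, 10.15, 239.46),
    dr_normal    = c(0.054, 0.069, 0.342, 30.04, 73.62, 17.10, 10.89, 240.69),
    dr_decreased = c(0.052, 0.062, 0.401, 29.04, 70.24, 17.10, 10.60, 236.31)
  )
  rownames(m) <- cohort_param_names()
  m
}

default_group_sds <- function() {
  m <- cbind(
    control      = c(0.004, 0.005, 0.132, 2.88, 5.59, 3.66, 1.49, 21.01),
    dr_normal    = c(0.005, 0.006, 0.117, 3.14, 4.82, 3.41, 2.51, 16.13),
    dr_decreased = c(0.006, 0.007, 0.097, 3.64, 6.21, 3.82, 2.36, 19.14)
  )
  rownames(m) <- cohort_param_names()
  m
}

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the published group-conditional means/SDs of the
#' source cohort: 33 control, 53 normal-BCVA and 36 decreased-BCVA
#' participants; imaging parameters per group; participant age and diabetes
#' duration; and the multivariate BCVA model (intercept 0.575, age 0.002,
#' DRCP vessel density -6.194, GCL-IPL thickness -0.004) with an optional
#' GCL-IPL x DRCP-density interaction (-0.083 on mean-centered predictors).
#'
#' @param n_subjects named integer vector: participants per group
#'   (`control`, `dr_normal`, `dr_decreased`).
#' @param prob_both_eyes probability a participant contributes both eyes;
#'   scalar or named per-group vector.
#' @param group_means,group_sds 8 x 3 matrices (parameters x groups) of
#'   Gaussian parameters for the imaging measurements.
#' @param age_means,age_sds,dm_means,dm_sds per-group participant-level
#'   Gaussian parameters (years); diabetes duration is truncated at 0.
#' @param bcva_coefficients named vector `(intercept, age, vd_drcp,
#'   gcl_ipl_um)` of the BCVA linear predictor.
#' @param interaction_coefficient coefficient of the centered
#'   `gcl_ipl_um x vd_drcp` product; set 0 to disable.
#' @param interaction_centers centering constants `(gcl_ipl_um, vd_drcp)`
#'   for the product term.
#' @param subject_effect_sd lambda in \[0, 1): the participant-shared share
#'   of each parameter's SD; intraclass correlation is `lambda^2`.
#' @param residual_sd eye-level BCVA residual SD, logMAR.
#' @param etdrs_probs 3 x 3 matrix of ETDRS-level (20 / 35 / 43-53)
#'   probabilities per group (control column ignored).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = c(control = 33, dr_normal = 53,
                                       dr_decreased = 36),
                        prob_both_eyes = c(control = 0, dr_normal = 35 / 53,
                                           dr_decreased = 8 / 36),
                        group_means = default_group_means(),
                        group_sds = default_group_sds(),
                        age_means = c(control = 56.94, dr_normal = 50.72,
                                      dr_decreased = 60.47),
                        age_sds = c(control = 7.32, dr_normal = 9.43,
                                    dr_decreased = 10.55),
                        dm_means = c(control = 0, dr_normal = 7.62,
                                     dr_decreased = 11.19),
                        dm_sds = c(control = 0, dr_normal = 5.27,
                                   dr_decreased = 7.21),
                        bcva_coefficients = c(intercept = 0.575,
                                              age = 0.002,
                                              vd_drcp = -6.194,
                                              gcl_ipl_um = -0.004),
                        interaction_coefficient = 0,
                        interaction_centers = c(gcl_ipl_um = 72.40,
                                                vd_drcp = 0.072),
                        subject_effect_sd = sqrt(0.5),
                        residual_sd = 0.03,
                        etdrs_probs = cbind(
                          control = c(1, 0, 0),
                          dr_normal = c(39, 33, 16) / 88,
                          dr_decreased = c(17, 19, 8) / 44),
                        seed = 1L) {
  grp <- cohort_group_names()
  if (length(prob_both_eyes) == 1) {
    prob_both_eyes <- stats::setNames(rep(prob_both_eyes, 3), grp)
  }
  assert_that(all(n_subjects[grp] > 0),
              "n_subjects must be positive for every group")
  assert_that(all(prob_both_eyes >= 0 & prob_both_eyes <= 1),
              "prob_both_eyes must be in [0, 1]")
  assert_that(all(group_sds >= 0) && all(age_sds >= 0) && all(dm_sds >= 0),
              "all SDs must be >= 0")
  assert_that(subject_effect_sd >= 0 && subject_effect_sd < 1,
              "subject_effect_sd must be in [0, 1)")
  assert_that(residual_sd >= 0, "residual_sd must be >= 0")
  assert_that(identical(rownames(group_means), cohort_param_names()) &&
                identical(rownames(group_sds), cohort_param_names()),
              "group_means/group_sds rows must be the 8 cohort parameters")
  structure(list(
    n_subjects = n_subjects[grp], prob_both_eyes = prob_both_eyes[grp],
    group_means = group_means[, grp], group_sds = group_sds[, grp],
    age_means = age_means[grp], age_sds = age_sds[grp],
    dm_means = dm_means[grp], dm_sds = dm_sds[grp],
    bcva_coefficients = bcva_coefficients,
    interaction_coefficient = interaction_coefficient,
    interaction_centers = interaction_centers,
    subject_effect_sd = subject_effect_sd, residual_sd = residual_sd,
    etdrs_probs = etdrs_probs[, grp], seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic eye-level cohort
#'
#' @param spec a [cohort_spec()].
#' @return list with `records` (data.frame, one row per eye, columns per
#'   [read_cohort_csv()]) and `truth` (the generating coefficients and
#'   variance components).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  params <- cohort_param_names()
  lambda <- spec$subject_effect_sd
  eye_share <- sqrt(1 - lambda^2)
  etdrs_levels <- c("20", "35", "43-53")
  records <- local_seed(spec$seed, {
    out <- list()
    sid0 <- 0L
    for (g in cohort_group_names()) {
      ns <- spec$n_subjects[[g]]
      both <- stats::rbinom(ns, 1, spec$prob_both_eyes[[g]]) == 1
      n_eyes_subj <- ifelse(both, 2L, 1L)
      subj_id <- sid0 + seq_len(ns)
      sid0 <- sid0 + ns
      age <- stats::rnorm(ns, spec$age_means[[g]], spec$age_sds[[g]])
      dm <- pmax(0, stats::rnorm(ns, spec$dm_means[[g]], spec$dm_sds[[g]]))
      etdrs <- if (g == "control") rep("", ns) else
        sample(etdrs_levels, ns, replace = TRUE, prob = spec$etdrs_probs[, g])
      z_subj <- stats::rnorm(ns)
      idx <- rep(seq_len(ns), n_eyes_subj)
      n_eyes <- length(idx)
      first <- !duplicated(idx)
      single_side <- sample(c("OD", "OS"), ns, replace = TRUE)
      eye <- ifelse(rep(n_eyes_subj, n_eyes_subj) == 2,
                    ifelse(first, "OD", "OS"), single_side[idx])
      df <- data.frame(
        subject_id = sprintf("S%04d", subj_id[idx]), eye = eye, group = g,
        age = age[idx], dm_duration = dm[idx], etdrs_level = etdrs[idx],
        stringsAsFactors = FALSE
      )
      for (p in params) {
        m <- spec$group_means[p, g]; s <- spec$group_sds[p, g]
        df[[p]] <- m + s * (lambda * z_subj[idx] +
                              eye_share * stats::rnorm(n_eyes))
      }
      out[[g]] <- df
    }
    df <- do.call(rbind, out)
    b <- spec$bcva_coefficients
    ctr <- spec$interaction_centers
    lp <- b[["intercept"]] + b[["age"]] * df$age +
      b[["vd_drcp"]] * df$vd_drcp + b[["gcl_ipl_um"]] * df$gcl_ipl_um +
      spec$interaction_coefficient *
        (df$gcl_ipl_um - ctr[["gcl_ipl_um"]]) * (df$vd_drcp - ctr[["vd_drcp"]])
    df$bcva_logmar <- lp + stats::rnorm(nrow(df), 0, spec$residual_sd)
    rownames(df) <- NULL
    df
  })
  assert_that(all(is.finite(records$bcva_logmar)),
              "generated logMAR values must be finite")
  list(
    records = records[, cohort_columns()],
    truth = list(
      coefficients = spec$bcva_coefficients,
      interaction_coefficient = spec$interaction_coefficient,
      interaction_centers = spec$interaction_centers,
      subject_effect_sd = spec$subject_effect_sd,
      icc = spec$subject_effect_sd^2,
      residual_sd = spec$residual_sd,
      group_means = spec$group_means, group_sds = spec$group_sds
    )
  )
}
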