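test_that("GEE with singleton clusters reproduces OLS to machine precision", {
  set.seed(21)
  n <- 150
  df <- data.frame(x1 = rnorm(n), x2 = runif(n), id = seq_len(n))
  df$y <- 0.5 - 1.2 * df$x1 + 0.3 * df$x2 + rnorm(n)
  fit <- gee_fit(y ~ x1 + x2, df, id = "id")
  ols <- lm(y ~ x1 + x2, df)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-12)
  expect_equal(fit$rho, 0)
})

test_that("confidence intervals are estimate +/- 1.96 SE on every fit", {
  rec <- quick_cohort(seed = 7)
  fit <- gee_fit(bcva_logmar ~ age + vd_drcp, rec)
  co <- fit$coefficients
  expect_equal(co$ci_lower, co$estimate - 1.96 * co$std_error)
  expect_equal(co$ci_upper, co$estimate + 1.96 * co$std_error)
  expect_error(gee_fit(bcva_logmar ~ vd_drcp + I(2 * vd_drcp), rec),
               "collinear")
})

test_that("exchangeable working correlation absorbs the subject effect", {
  ch <- generate_cohort(cohort_spec(
    n_subjects = c(control = 2, dr_normal = 300, dr_decreased = 300),
    prob_both_eyes = 1, seed = 13))
  dr <- ch$records[ch$records$group != "control", ]
  fit <- gee_fit(gcl_ipl_um ~ age, dr)
  expect_gt(fit$rho, 0.3)  # strong inter-eye correlation detected
})

test_that("group_compare picks sensible tests and detects true differences", {
  rec <- quick_cohort(seed = 8)
  dr <- rec[rec$group != "control", ]
  # algebraic identity: two-group ANOVA F == pooled t^2
  p_t <- group_compare(dr, "vd_drcp", test = "t")$p_value
  p_f <- group_compare(dr, "vd_drcp", test = "anova")$p_value
  expect_equal(p_t, p_f, tolerance = 1e-12)
  # power at the published effect size (scaled down from the spec's
  # 5,000/group for runtime; power is still ~1)
  big <- generate_cohort(cohort_spec(
    n_subjects = c(control = 2, dr_normal = 500, dr_decreased = 500),
    seed = 14))$records
  big <- big[big$group != "control", ]
  expect_lt(group_compare(big, "vd_drcp", test = "t")$p_value, 0.001)
  # categorical path
  out <- group_compare(dr, "etdrs_level", test = "chi2")
  expect_equal(out$test, "chi2")
  expect_error(group_compare(transform(dr, k = 1), "k", test = "t"),
               "constant")
})

test_that("null p-values are uniform (Kolmogorov-Smirnov calibration)", {
  set.seed(22)
  ps <- replicate(400, {
    v <- rnorm(40)
    g <- rep(c("a", "b"), each = 20)
    group_compare(data.frame(v = v, g = g), "v", grouping = g,
                  test = "t")$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("adjusted comparisons control type I error and recover covariates", {
  # generator with no group effect but a strong age effect
  set.seed(23)
  reps <- 40
  hit <- 0; cov_ok <- 0
  for (i in 1:reps) {
    n_subj <- 150
    id <- rep(seq_len(n_subj), each = 2)
    age <- rep(rnorm(n_subj, 55, 8), each = 2)
    g <- rep(sample(c("g1", "g2", "g3"), n_subj, replace = TRUE), each = 2)
    u <- rep(rnorm(n_subj), each = 2)
    df <- data.frame(subject_id = id, group = g, age = age,
                     dm_duration = 0 * age,
                     y = 100 + 0.8 * age + 2 * u + rnorm(2 * n_subj))
    res <- adjusted_group_compare(df, "y", covariates = "age")
    if (res$overall_p > 0.05) hit <- hit + 1
    co <- res$fit$coefficients
    a <- co[co$term == "age", ]
    if (abs(a$estimate - 0.8) < 2 * a$std_error) cov_ok <- cov_ok + 1
  }
  expect_gte(hit / reps, 0.85)     # nominal 95%, 40-replicate slack
  expect_gte(cov_ok / reps, 0.85)
})

test_that("univariate screen flags the published predictors with signs", {
  set.seed(24)
  reps <- 30
  flagged <- matrix(0, reps, 3,
                    dimnames = list(NULL, c("age", "vd_drcp", "gcl_ipl_um")))
  signs_ok <- TRUE
  for (i in 1:reps) {
    rec <- generate_cohort(cohort_spec(seed = sample.int(1e6, 1)))$records
    dr <- rec[rec$group != "control", ]
    uni <- univariate_screen(dr,
      predictors = c("age", "vd_drcp", "gcl_ipl_um", "eye"))
    for (p in colnames(flagged)) {
      row <- uni[uni$predictor == p, ]
      if (row$significant) {
        flagged[i, p] <- 1
        sign_true <- c(age = 1, vd_drcp = -1, gcl_ipl_um = -1)[[p]]
        if (sign(row$estimate) != sign_true) signs_ok <- FALSE
      }
    }
  }
  expect_true(all(colMeans(flagged) >= 0.9))
  expect_true(signs_ok)
})

test_that("pure-noise predictors are flagged at about the nominal rate", {
  set.seed(25)
  hits <- replicate(100, {
    rec <- quick_cohort(seed = sample.int(1e6, 1))
    rec$noise <- rnorm(nrow(rec))
    univariate_screen(rec, predictors = "noise")$significant
  })
  expect_lt(mean(hits), 0.15)
})

test_that("backward elimination refits are idempotent", {
  rec <- generate_cohort(cohort_spec(
    n_subjects = c(control = 2, dr_normal = 400, dr_decreased = 400),
    seed = 26))$records
  dr <- rec[rec$group != "control", ]
  dr$pure_noise <- rnorm(nrow(dr))
  fit <- multivariate_model(dr, c("age", "vd_drcp", "gcl_ipl_um",
                                  "pure_noise"))
  kept <- setdiff(fit$coefficients$term, "(Intercept)")
  refit <- multivariate_model(dr, kept)
  m <- match(fit$coefficients$term, refit$coefficients$term)
  expect_equal(refit$coefficients$estimate[m], fit$coefficients$estimate,
               tolerance = 1e-6)
  expect_true(all(fit$coefficients$p_value[-1] < 0.05))
})

test_that("orthogonal predictors give multivariate == univariate estimates", {
  set.seed(27)
  n <- 2000
  df <- data.frame(subject_id = seq_len(n), x1 = rnorm(n), x2 = rnorm(n))
  df$bcva_logmar <- 0.1 + 0.05 * df$x1 - 0.03 * df$x2 + rnorm(n, 0, 0.05)
  multi <- multivariate_model(df, c("x1", "x2"))
  uni <- univariate_screen(df, predictors = c("x1", "x2"))
  for (p in c("x1", "x2")) {
    b_m <- multi$coefficients$estimate[multi$coefficients$term == p]
    b_u <- uni$estimate[uni$predictor == p]
    expect_equal(b_m, b_u, tolerance = 0.05)
  }
})

test_that("elimination down to nothing returns intercept-only with warning", {
  set.seed(28)
  rec <- quick_cohort(seed = 31)
  rec$junk <- rnorm(nrow(rec))
  rec$junk2 <- rnorm(nrow(rec))
  # outcome pure noise, junk predictors: expect eventual empty model
  rec$bcva_logmar <- rnorm(nrow(rec))
  got_warning <- FALSE
  fit <- withCallingHandlers(
    multivariate_model(rec, c("junk", "junk2")),
    warning = function(w) {
      got_warning <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (got_warning) {
    expect_equal(fit$coefficients$term, "(Intercept)")
  } else {
    succeed("junk predictor survived by chance at alpha = 0.05")
  }
})

test_that("interaction product term is the centered element-wise product", {
  rec <- quick_cohort(seed = 29)
  dr <- rec[rec$group != "control", ]
  fit <- interaction_model(dr)
  ctr <- attr(fit, "centers")
  expect_equal(unname(ctr),
               c(mean(dr$gcl_ipl_um), mean(dr$vd_drcp)))
  expect_true("gcl_ipl_um_x_vd_drcp" %in% fit$coefficients$term)
})

test_that("ROC: separation, null calibration, and the U-statistic identity", {
  # perfect separation
  df <- data.frame(x = c(rnorm(50, 0), rnorm(50, 100)),
                   y = rep(c(FALSE, TRUE), each = 50))
  r <- roc_cutoff(df, "x", df$y)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity + r$specificity - 1, 1)  # Youden J = 1
  # independent parameter: AUC ~ 0.5 at n = 2000
  set.seed(30)
  df2 <- data.frame(x = rnorm(2000), y = rbinom(2000, 1, 0.4) == 1)
  r2 <- roc_cutoff(df2, "x", df2$y)
  expect_lt(abs(r2$auc - 0.5), 0.03)
  # AUC == U / (n1 n0) exactly, including ties (direction-aware)
  for (s in 1:5) {
    set.seed(s)
    x <- round(rnorm(200), 1)
    y <- rbinom(200, 1, 0.5) == 1
    r3 <- roc_cutoff(data.frame(x = x, y = y), "x", y)
    u <- unname(stats::wilcox.test(x[y], x[!y], exact = FALSE)$statistic) /
      (sum(y) * sum(!y))
    expect_equal(r3$auc, max(u, 1 - u), tolerance = 1e-12)
  }
  expect_error(roc_cutoff(data.frame(x = 1:5, y = TRUE), "x", rep(TRUE, 5)),
               "classes")
})
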