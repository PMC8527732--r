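test_that("normative reference equals a direct two-pass computation", {
  ctrl <- quick_cohort(seed = 2)
  ctrl <- ctrl[ctrl$group == "control", ]
  ref <- fit_normative_reference(ctrl)
  # independent two-pass oracle
  v <- ctrl$vd_drcp
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  expect_equal(ref$mean[["vd_drcp"]], m, tolerance = 1e-14)
  expect_equal(ref$sd[["vd_drcp"]], s, tolerance = 1e-14)
  expect_error(fit_normative_reference(ctrl[1, ]), "at least 2")
  ctrl2 <- ctrl
  ctrl2$opl_um <- 10
  expect_error(fit_normative_reference(ctrl2), "zero variance")
})

test_that("the 1.96 SD rule flags strictly beyond the band, per direction", {
  ref <- structure(list(
    mean = sapply(names(octaphen:::phenotype_directions()), function(p) {
      octaphen:::default_group_means()[p, "control"]
    }),
    sd = sapply(names(octaphen:::phenotype_directions()), function(p) {
      octaphen:::default_group_sds()[p, "control"]
    }),
    direction = octaphen:::phenotype_directions(), n = 33, z = 1.96
  ), class = "normative_reference")
  # published reference: vd_drcp 0.072 +/- 0.005 -> threshold 0.0622
  rec <- control_mean_record()
  rec$vd_drcp <- 0.060
  fl <- classify_eye(rec, ref)
  expect_true(fl[["vd_drcp_decrease"]])
  expect_true(fl[["ischemia"]])
  expect_false(fl[["neurodegeneration"]])
  # exactly at the threshold: strict inequality, no flag
  rec$vd_drcp <- 0.072 - 1.96 * 0.005
  expect_false(classify_eye(rec, ref)[["vd_drcp_decrease"]])
  # at the mean: nothing flags
  expect_false(any(classify_eye(control_mean_record(), ref)))
})

test_that("missing parameters break composites loudly, not silently", {
  ctrl <- quick_cohort(seed = 2)
  ref <- fit_normative_reference(ctrl[ctrl$group == "control", ])
  rec <- control_mean_record()
  rec$rnfl_um <- NULL
  expect_error(classify_eye(rec, ref), "neurodegeneration")
})

test_that("composite flags are monotone in their components", {
  ctrl <- quick_cohort(seed = 4)
  ref <- fit_normative_reference(ctrl[ctrl$group == "control", ])
  flags <- classify_cohort(ctrl, ref)
  # forcing any component on can only keep composites on
  forced <- ctrl
  forced$faz_area_mm2 <- ref$mean[["faz_area_mm2"]] +
    3 * ref$sd[["faz_area_mm2"]]
  flags2 <- classify_cohort(forced, ref)
  expect_true(all(flags2$ischemia >= flags$ischemia))
  expect_true(all(flags2$ischemia))
})

test_that("prevalence CIs reproduce the published table cells exactly", {
  cell <- function(count, n) {
    ci <- prevalence_with_ci(count, n)
    c(ci$percent, ci$lower, ci$upper)
  }
  expect_equal(cell(17, 88), c(19.3, 11.1, 27.6))
  expect_equal(cell(2, 88), c(2.3, 0, 5.4))     # clipped lower bound
  expect_equal(cell(0, 88), c(0, 0, 0))
  expect_equal(cell(21, 44), c(47.7, 33.0, 62.5))
  expect_equal(cell(16, 24), c(66.7, 47.8, 85.5))
  expect_error(prevalence_with_ci(1, 0), "positive")
  expect_error(prevalence_with_ci(5, 4), "integer")
})

test_that("Fisher exact p equals brute-force enumeration and is symmetric", {
  # independent oracle: enumerate every table with the observed margins
  enum_p <- function(tab) {
    rs <- rowSums(tab); cs <- colSums(tab)
    p_of <- function(a) {
      b <- rs[1] - a; c <- cs[1] - a; d <- rs[2] - c
      if (b < 0 || c < 0 || d < 0) return(NA_real_)
      exp(lgamma(rs[1] + 1) + lgamma(rs[2] + 1) + lgamma(cs[1] + 1) +
            lgamma(cs[2] + 1) - lgamma(sum(tab) + 1) - lgamma(a + 1) -
            lgamma(b + 1) - lgamma(c + 1) - lgamma(d + 1))
    }
    probs <- vapply(0:min(rs[1], cs[1]), p_of, numeric(1))
    probs <- probs[!is.na(probs)]
    sum(probs[probs <= p_of(tab[1, 1]) * (1 + 1e-7)])
  }
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8) + 1, 2, 2)
    p <- compare_proportions(tab)$p_value
    expect_equal(p, enum_p(tab), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-8)
    expect_equal(compare_proportions(tab[2:1, ])$p_value, p,
                 tolerance = 1e-12)
    expect_equal(compare_proportions(tab[, 2:1])$p_value, p,
                 tolerance = 1e-12)
  }
  expect_error(compare_proportions(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("2 x k tables fall back to Pearson's chi-squared", {
  tab <- matrix(c(8, 48, 13, 39, 17, 7), 2, 3)
  out <- compare_proportions(tab)
  expect_equal(out$method, "chisq")
  expect_equal(out$p_value, stats::chisq.test(tab, correct = FALSE)$p.value,
               tolerance = 1e-12)
})

test_that("phenotype_summary mirrors the published table layout", {
  rec <- quick_cohort(seed = 6)
  dr <- rec[rec$group != "control", ]
  ref <- fit_normative_reference(rec[rec$group == "control", ])
  flags <- classify_cohort(dr, ref)
  strata <- ifelse(dr$bcva_logmar > 0, "decreased", "normal")
  tab <- phenotype_summary(flags, strata)
  expect_equal(nrow(tab), 11L)  # 8 components + 3 composites
  expect_true(all(c("count_decreased", "percent_normal", "p_value") %in%
                    names(tab)))
  # counts consistent with the flags they summarize
  expect_equal(tab$count_normal[tab$flag == "ischemia"],
               sum(flags$ischemia[strata == "normal"]))
})
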