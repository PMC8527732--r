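# Normative phenotype classification.
#
# The healthy-control mean and SD of each parameter define the reference
# band; an eye is flagged when its value lies strictly beyond
# mean +/- 1.96 SD in the parameter's abnormal direction. Component flags
# combine into three composite phenotypes:
#   ischemia          = VD decrease (either plexus) OR FAZ-area increase
#   neurodegeneration = RNFL OR GCL-IPL thinning
#   subclinical edema = INL OR OPL OR total retinal thickening

phenotype_directions <- function() {
  c(vd_srcp = "below", vd_drcp = "below", faz_area_mm2 = "above",
    rnfl_um = "below", gcl_ipl_um = "below",
    inl_um = "above", opl_um = "above", total_um = "above")
}

flag_names <- function() {
  c("vd_srcp_decrease", "vd_drcp_decrease", "faz_increase",
    "rnfl_thinning", "gcl_ipl_thinning", "inl_thickening",
    "opl_thickening", "total_thickening")
}

#' Fit the normative reference from control eyes
#'
#' Sample mean and SD per parameter over the control records.
#'
#' @param control_records data.frame of control eyes with the eight
#'   parameters (`vd_srcp`, `vd_drcp`, `faz_area_mm2`, `rnfl_um`,
#'   `gcl_ipl_um`, `inl_um`, `opl_um`, `total_um`).
#' @return an object of class `normative_reference`: per-parameter `mean`,
#'   `sd` and `direction` of abnormality.
#' @export
fit_normative_reference <- function(control_records) {
  params <- names(phenotype_directions())
  assert_that(all(params %in% names(control_records)),
              "control records missing parameters")
  assert_that(nrow(control_records) >= 2,
              "need at least 2 control eyes to estimate an SD")
  vals <- control_records[, params]
  assert_that(all(stats::complete.cases(vals)),
              "control records contain missing parameter values")
  mu <- vapply(vals, mean, numeric(1))
  s <- vapply(vals, stats::sd, numeric(1))
  if (any(s <= 0)) {
    stop("zero variance in control parameter(s): ",
         paste(params[s <= 0], collapse = ", "), call. = FALSE)
  }
  structure(list(mean = mu, sd = s, direction = phenotype_directions(),
                 n = nrow(control_records), z = 1.96),
            class = "normative_reference")
}

#' Classify eyes into phenotype flags
#'
#' A component flag is `TRUE` iff the value lies strictly beyond
#' `mean +/- 1.96 SD` in the abnormal direction. `classify_eye` takes one
#' record (a one-row data.frame or named list); `classify_cohort` a whole
#' table. A missing parameter yields an `NA` component flag and an error
#' for any composite that uses it.
#'
#' @param record one eye's measurements.
#' @param reference a [fit_normative_reference()] result.
#' @return named logical vector of the eight component flags plus
#'   `ischemia`, `neurodegeneration`, `subclinical_edema`.
#' @export
classify_eye <- function(record, reference) {
  flags <- classify_cohort(as.data.frame(record, stringsAsFactors = FALSE),
                           reference)
  unlist(flags[1, ])
}

#' @rdname classify_eye
#' @param records data.frame of eyes.
#' @export
classify_cohort <- function(records, reference) {
  stopifnot(inherits(reference, "normative_reference"))
  params <- names(reference$direction)
  z <- reference$z
  comp <- lapply(params, function(p) {
    if (is.null(records[[p]])) return(rep(NA, nrow(records)))
    v <- records[[p]]
    if (reference$direction[[p]] == "below") {
      v < reference$mean[[p]] - z * reference$sd[[p]]
    } else {
      v > reference$mean[[p]] + z * reference$sd[[p]]
    }
  })
  flags <- as.data.frame(stats::setNames(comp, flag_names()))
  safe_or <- function(cols, composite) {
    m <- as.matrix(flags[, cols, drop = FALSE])
    if (anyNA(m)) {
      stop("cannot form composite '", composite,
           "': component flag(s) undefined (missing parameter)",
           call. = FALSE)
    }
    apply(m, 1, any)
  }
  flags$ischemia <- safe_or(
    c("vd_srcp_decrease", "vd_drcp_decrease", "faz_increase"), "ischemia")
  flags$neurodegeneration <- safe_or(
    c("rnfl_thinning", "gcl_ipl_thinning"), "neurodegeneration")
  flags$subclinical_edema <- safe_or(
    c("inl_thickening", "opl_thickening", "total_thickening"),
    "subclinical_edema")
  flags
}

#' Prevalence with a Wald 95% confidence interval
#'
#' Percent = 100 * count / n; the interval is the normal approximation
#' `p +/- 1.96 sqrt(p(1-p)/n)`, clipped to \[0, 100\] and rounded
#' half-away-from-zero to one decimal (the convention that reproduces
#' published prevalence tables, including clipped lower bounds).
#'
#' @param count number of flagged eyes.
#' @param n denominator.
#' @return list of class `proportion_ci`: `count`, `n`, `percent`,
#'   `lower`, `upper` (percent scale, rounded to 1 decimal).
#' @export
prevalence_with_ci <- function(count, n) {
  assert_that(n > 0, "n must be positive")
  assert_that(count >= 0 && count <= n && count == round(count),
              "count must be an integer in [0, n]")
  p <- count / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  structure(list(
    count = as.integer(count), n = as.integer(n),
    percent = round_half_up(100 * p, 1),
    lower = round_half_up(100 * max(0, p - half), 1),
    upper = round_half_up(100 * min(1, p + half), 1)
  ), class = "proportion_ci")
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed that of the observed table.
fisher_exact_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-squared p-value (no continuity correction).
pearson_chisq_p <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Compare proportions across groups
#'
#' For a 2x2 table the default is the two-sided Fisher exact test computed
#' by direct hypergeometric enumeration (sparse phenotype cells make the
#' asymptotic chi-squared unreliable); Pearson's chi-squared is available
#' by flag and is the default for 2xk tables.
#'
#' @param tab matrix of non-negative integer counts, 2 rows (flagged / not
#'   flagged) x k group columns, or the transpose.
#' @param method `"auto"`, `"fisher"` (2x2 only) or `"chisq"`.
#' @return list with `p_value` and `method`.
#' @export
compare_proportions <- function(tab, method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  assert_that(all(tab >= 0) && all(tab == round(tab)),
              "counts must be non-negative integers")
  assert_that(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
              "degenerate margins: every row and column needs a positive sum")
  is_2x2 <- all(dim(tab) == 2)
  if (method == "auto") method <- if (is_2x2) "fisher" else "chisq"
  if (method == "fisher") {
    assert_that(is_2x2, "Fisher exact test implemented for 2x2 tables only")
    list(p_value = fisher_exact_p(tab), method = "fisher")
  } else {
    list(p_value = pearson_chisq_p(tab), method = "chisq")
  }
}

#' Phenotype prevalence summary table
#'
#' For each component and composite flag, counts and Wald CIs per stratum
#' plus the between-stratum test (Fisher exact for two strata, chi-squared
#' otherwise). Strata with identical zero counts everywhere report `NA`
#' p-values.
#'
#' @param flags data.frame from [classify_cohort()].
#' @param strata factor/character vector of the same length assigning each
#'   eye to a stratum.
#' @return data.frame, one row per flag, with `count_<s>`, `percent_<s>`,
#'   `lower_<s>`, `upper_<s>` per stratum and `p_value`.
#' @export
phenotype_summary <- function(flags, strata) {
  strata <- as.factor(strata)
  assert_that(length(strata) == nrow(flags),
              "strata must match the number of eyes")
  all_flags <- c(flag_names(), "ischemia", "neurodegeneration",
                 "subclinical_edema")
  rows <- lapply(all_flags, function(fl) {
    v <- flags[[fl]]
    counts <- tapply(v, strata, sum)
    ns <- tapply(v, strata, length)
    row <- list(flag = fl)
    for (s in levels(strata)) {
      ci <- prevalence_with_ci(counts[[s]], ns[[s]])
      row[[paste0("count_", s)]] <- ci$count
      row[[paste0("percent_", s)]] <- ci$percent
      row[[paste0("lower_", s)]] <- ci$lower
      row[[paste0("upper_", s)]] <- ci$upper
    }
    tab <- rbind(flagged = counts, not_flagged = ns - counts)
    row$p_value <- if (all(counts == 0) || all(counts == ns)) NA_real_ else
      round_half_up(compare_proportions(tab)$p_value, 3)
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
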