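# Statistical chain on eye-level tables: group comparisons (raw and
# covariate-adjusted), clustered univariate screening and multivariate
# modelling of visual acuity, the ischemia x neurodegeneration interaction,
# and ROC cutoffs for visual impairment.

# Numeric design value for a predictor: OD/OS coded 0/1, ETDRS severity
# bands coded ordinally 1..3, everything else taken as numeric.
predictor_values <- function(records, name) {
  if (name == "eye") return(as.numeric(records$eye == "OS"))
  if (name == "etdrs_level") {
    code <- match(as.character(records$etdrs_level), c("20", "35", "43-53"))
    return(as.numeric(code))
  }
  v <- records[[name]]
  assert_that(!is.null(v), paste("no column", name))
  as.numeric(v)
}

# Shapiro-Wilk normality screen (per group; subsamples above the test's
# 5000-value limit).
is_plausibly_normal <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  stats::shapiro.test(x)$p.value >= alpha
}

#' Unadjusted group comparison of one parameter
#'
#' Auto mode uses the t-test (2 groups) or one-way ANOVA (>2) when every
#' group passes a Shapiro-Wilk screen at alpha = 0.05, Kruskal-Wallis
#' otherwise, and a chi-squared contingency test for categorical
#' parameters.
#'
#' @param records data.frame of eyes.
#' @param parameter column to compare (categorical columns are character/
#'   factor).
#' @param grouping column (or vector) defining groups.
#' @param test `"auto"`, `"t"`, `"anova"`, `"kw"` or `"chi2"`.
#' @return list with `p_value`, `test`, and per-group `summaries`
#'   (mean, sd, n for continuous parameters; counts otherwise).
#' @export
group_compare <- function(records, parameter, grouping = "group",
                          test = c("auto", "t", "anova", "kw", "chi2")) {
  test <- match.arg(test)
  g <- if (length(grouping) == 1 && is.character(grouping))
    records[[grouping]] else grouping
  g <- droplevels(as.factor(g))
  assert_that(nlevels(g) >= 2, "need at least two groups")
  assert_that(all(table(g) >= 2), "need at least two eyes per group")
  v <- records[[parameter]]
  categorical <- is.character(v) || is.factor(v)
  if (test == "auto") {
    test <- if (categorical) "chi2"
    else if (all(tapply(v, g, is_plausibly_normal)))
      (if (nlevels(g) == 2) "t" else "anova") else "kw"
  }
  if (test == "chi2") {
    tab <- table(v, g)
    return(list(p_value = pearson_chisq_p(unclass(tab)), test = "chi2",
                summaries = tab))
  }
  v <- as.numeric(v)
  assert_that(stats::sd(v) > 0, "parameter constant across all groups")
  summaries <- do.call(rbind, lapply(levels(g), function(l) {
    data.frame(group = l, mean = mean(v[g == l]), sd = stats::sd(v[g == l]),
               n = sum(g == l), stringsAsFactors = FALSE)
  }))
  p <- switch(test,
    t = stats::t.test(v ~ g, var.equal = TRUE)$p.value,
    anova = stats::anova(stats::lm(v ~ g))[["Pr(>F)"]][1],
    kw = stats::kruskal.test(v, g)$p.value
  )
  list(p_value = p, test = test, summaries = summaries)
}

#' Covariate-adjusted group comparison
#'
#' Estimating-equation regression of the parameter on group indicators
#' plus covariates, clustered by participant with exchangeable working
#' correlation and robust errors. Reports the overall Wald test of the
#' group effect and all pairwise group contrasts.
#'
#' @param records data.frame of eyes.
#' @param parameter outcome column.
#' @param covariates adjustment columns (default age and diabetes
#'   duration).
#' @param grouping grouping column.
#' @param id cluster column.
#' @return list with `overall_p`, `pairwise` (data.frame of contrasts),
#'   and the underlying `fit`.
#' @export
adjusted_group_compare <- function(records, parameter,
                                   covariates = c("age", "dm_duration"),
                                   grouping = "group", id = "subject_id") {
  for (cv in covariates) {
    assert_that(all(is.finite(records[[cv]])),
                paste("covariate", cv, "has non-finite values"))
  }
  df <- records
  df$.y <- as.numeric(df[[parameter]])
  df$.g <- droplevels(as.factor(df[[grouping]]))
  fml <- stats::as.formula(paste(".y ~ .g +",
                                 paste(covariates, collapse = " + ")))
  fit <- gee_fit(fml, df, id = id)
  lv <- levels(df$.g)
  terms <- paste0(".g", lv[-1])
  overall <- gee_wald_test(fit, terms)
  cmb <- utils::combn(lv, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    L <- numeric(nrow(fit$coefficients))
    if (a != lv[1]) L[match(paste0(".g", a), fit$coefficients$term)] <- -1
    if (b != lv[1]) L[match(paste0(".g", b), fit$coefficients$term)] <- 1
    ct <- gee_contrast(fit, L)
    data.frame(group_a = a, group_b = b, estimate = ct$estimate,
               std_error = ct$std_error, p_value = ct$p_value,
               stringsAsFactors = FALSE)
  }))
  list(overall_p = overall$p_value, pairwise = pairwise, fit = fit)
}

#' Univariate clustered screening of BCVA predictors
#'
#' One clustered linear model per predictor with BCVA as the outcome;
#' predictors with p < alpha are flagged for the multivariate model.
#'
#' @param records data.frame of eyes.
#' @param predictors predictor names (`eye` and `etdrs_level` are coded
#'   0/1 and ordinally).
#' @param outcome outcome column.
#' @param alpha screening level.
#' @param id cluster column.
#' @return data.frame: one row per predictor with estimate, robust SE,
#'   95% CI, p-value and `significant`.
#' @export
univariate_screen <- function(records,
                              predictors = c("age", "dm_duration",
                                             "etdrs_level", "eye",
                                             "vd_srcp", "vd_drcp",
                                             "faz_area_mm2", "rnfl_um",
                                             "gcl_ipl_um", "inl_um",
                                             "opl_um", "total_um"),
                              outcome = "bcva_logmar", alpha = 0.05,
                              id = "subject_id") {
  assert_that(all(is.finite(records[[outcome]])), "outcome must be finite")
  rows <- lapply(predictors, function(p) {
    x <- predictor_values(records, p)
    assert_that(stats::sd(x, na.rm = TRUE) > 0,
                paste("constant predictor:", p))
    df <- data.frame(.y = records[[outcome]], .x = x,
                     .id = records[[id]])
    df <- df[stats::complete.cases(df), ]
    fit <- gee_fit(.y ~ .x, df, id = df$.id)
    co <- fit$coefficients[fit$coefficients$term == ".x", ]
    data.frame(predictor = p, estimate = co$estimate,
               std_error = co$std_error, ci_lower = co$ci_lower,
               ci_upper = co$ci_upper, p_value = co$p_value,
               significant = co$p_value < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Build a design data.frame of coded predictors for gee_fit.
coded_frame <- function(records, predictors, outcome, id) {
  df <- data.frame(.y = records[[outcome]])
  for (p in predictors) df[[p]] <- predictor_values(records, p)
  df$.id <- records[[id]]
  df[stats::complete.cases(df), ]
}

#' Final multivariate BCVA model with backward elimination
#'
#' Fits a clustered linear model on the selected predictors, then
#' backward-eliminates the least significant term while any p >= alpha,
#' refitting at each step, until all retained terms are significant.
#'
#' @param records data.frame of eyes.
#' @param selected_predictors starting predictor set (e.g. the significant
#'   rows of [univariate_screen()]).
#' @param outcome outcome column.
#' @param alpha retention level.
#' @param id cluster column.
#' @return a [gee_fit()] with attribute `eliminated` listing dropped
#'   predictors in order. If elimination empties the model, an
#'   intercept-only fit is returned with a warning.
#' @export
multivariate_model <- function(records, selected_predictors,
                               outcome = "bcva_logmar", alpha = 0.05,
                               id = "subject_id") {
  assert_that(length(selected_predictors) >= 1,
              "need at least one selected predictor")
  current <- selected_predictors
  eliminated <- character(0)
  repeat {
    df <- coded_frame(records, current, outcome, id)
    fml <- stats::as.formula(paste(".y ~", paste(current, collapse = " + ")))
    fit <- gee_fit(fml, df, id = df$.id)
    co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    if (all(co$p_value < alpha)) break
    worst <- co$term[which.max(co$p_value)]
    eliminated <- c(eliminated, worst)
    current <- setdiff(current, worst)
    if (length(current) == 0) {
      warning("backward elimination removed every predictor; ",
              "returning intercept-only model", call. = FALSE)
      df <- coded_frame(records, selected_predictors, outcome, id)
      fit <- gee_fit(.y ~ 1, df, id = df$.id)
      break
    }
  }
  attr(fit, "eliminated") <- eliminated
  fit
}

#' Interaction model for GCL-IPL thickness x DRCP vessel density
#'
#' Adds the product of the mean-centered predictors to the multivariate
#' model and reports the interaction coefficient.
#'
#' @param records data.frame of eyes.
#' @param base_predictors main-effect predictors.
#' @param interaction_pair the two predictors whose centered product is
#'   added.
#' @param centers optional named centering constants for the pair;
#'   defaults to the sample means. Supplying the constants of a known
#'   data-generating model makes all main effects directly comparable.
#' @param outcome outcome column.
#' @param id cluster column.
#' @return a [gee_fit()]; the product term is named
#'   `<a>_x_<b>` and carried in attribute `interaction_term`, with the
#'   centering constants in attribute `centers`.
#' @export
interaction_model <- function(records,
                              base_predictors = c("age", "vd_drcp",
                                                  "gcl_ipl_um"),
                              interaction_pair = c("gcl_ipl_um", "vd_drcp"),
                              centers = NULL,
                              outcome = "bcva_logmar", id = "subject_id") {
  assert_that(all(interaction_pair %in% names(records)),
              "interaction predictors missing from records")
  df <- coded_frame(records, unique(c(base_predictors, interaction_pair)),
                    outcome, id)
  a <- interaction_pair[1]; b <- interaction_pair[2]
  if (is.null(centers)) {
    centers <- c(mean(df[[a]]), mean(df[[b]]))
    names(centers) <- interaction_pair
  } else {
    centers <- centers[interaction_pair]
  }
  prod_name <- paste0(a, "_x_", b)
  df[[prod_name]] <- (df[[a]] - centers[1]) * (df[[b]] - centers[2])
  assert_that(stats::sd(df[[prod_name]]) > 0,
              "degenerate variance of the product term")
  fml <- stats::as.formula(
    paste(".y ~", paste(c(base_predictors, prod_name), collapse = " + ")))
  fit <- gee_fit(fml, df, id = df$.id)
  attr(fit, "interaction_term") <- prod_name
  attr(fit, "centers") <- centers
  fit
}

#' ROC analysis and optimal cutoff for visual impairment
#'
#' Empirical ROC over all observed thresholds; AUC by the trapezoid rule
#' (equal to the Mann-Whitney U statistic divided by n1*n2); the optimal
#' cutoff maximizes Youden's J. If AUC < 0.5 with the higher-is-abnormal
#' convention, the direction is flipped.
#'
#' @param records data.frame of eyes.
#' @param parameter predictor column.
#' @param outcome logical vector (or column name) indicating decreased
#'   BCVA; defaults to `bcva_logmar > 0`.
#' @return an object of class `roc_result`: `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `direction` (`">="` means values at or
#'   above the cutoff are called abnormal), `criterion = "youden"`.
#' @export
roc_cutoff <- function(records, parameter, outcome = NULL) {
  x <- as.numeric(records[[parameter]])
  y <- if (is.null(outcome)) records$bcva_logmar > 0
  else if (is.character(outcome) && length(outcome) == 1)
    as.logical(records[[outcome]]) else as.logical(outcome)
  ok <- is.finite(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  assert_that(any(y) && any(!y), "both outcome classes must be present")
  roc_one <- function(sign_flip) {
    v <- if (sign_flip) -x else x
    thr <- sort(unique(v))
    n1 <- sum(y); n0 <- sum(!y)
    # call abnormal when value >= cutoff
    tpr <- vapply(thr, function(t) sum(v >= t & y) / n1, numeric(1))
    fpr <- vapply(thr, function(t) sum(v >= t & !y) / n0, numeric(1))
    tpr <- c(1, tpr, 0); fpr <- c(1, fpr, 0)
    o <- order(fpr, tpr)
    fpr <- fpr[o]; tpr <- tpr[o]
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    j <- vapply(seq_along(thr), function(i) {
      sum(v >= thr[i] & y) / n1 - sum(v >= thr[i] & !y) / n0
    }, numeric(1))
    best <- which.max(j)
    list(auc = auc, cutoff = thr[best],
         sensitivity = sum(v >= thr[best] & y) / n1,
         specificity = sum(v < thr[best] & !y) / n0)
  }
  r <- roc_one(FALSE)
  direction <- ">="
  if (r$auc < 0.5) {
    r <- roc_one(TRUE)
    r$cutoff <- -r$cutoff
    direction <- "<="
  }
  structure(list(auc = r$auc, cutoff = r$cutoff,
                 sensitivity = r$sensitivity, specificity = r$specificity,
                 direction = direction, criterion = "youden",
                 parameter = parameter), class = "roc_result")
}
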