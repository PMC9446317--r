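.shape_features <- c("n_components", "volume_ml", "surface_area_mm2",
                     "sphericity", "obb_volume_ml", "lesion_obb_ratio")
.clinical_continuous <- c("age", "nihss")
.binary_features <- c("female", "cortical_involved", "multiple_territories",
                      "bilateral")

# multivariate shape model: surface area stays out (collinear with volume)
.default_shape_model <- c("n_components", "volume_ml", "sphericity",
                          "obb_volume_ml", "lesion_obb_ratio")

#' Prepare cohort features for logistic modelling
#'
#' Continuous shape descriptors are natural-log transformed (they are
#' strongly right-skewed) and then standardized to z-scores over the
#' analyzed rows; continuous clinical covariates (age, NIHSS) are
#' z-scored without the log; binary indicators are left untouched. After
#' this step every continuous coefficient is a log odds ratio per SD, so
#' effect sizes are comparable across variables.
#'
#' @param cohort data.frame with the cohort columns (see
#'   [simulate_cohort()]); shape descriptors must be positive.
#' @return The cohort with transformed columns; attribute `prepared` is
#'   set, and per-column centre/scale are stored in attribute `scaling`.
#' @export
prepare_features <- function(cohort) {
  shape_cols <- intersect(.shape_features, names(cohort))
  clin_cols <- intersect(.clinical_continuous, names(cohort))
  scaling <- list()
  for (cl in shape_cols) {
    x <- cohort[[cl]]
    if (any(!is.na(x) & x <= 0)) {
      stopf("shape descriptor '%s' has non-positive values; cannot log", cl)
    }
    x <- log(x)
    mu <- mean(x, na.rm = TRUE); sdv <- sd(x, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) stopf("zero variance in '%s'", cl)
    cohort[[cl]] <- (x - mu) / sdv
    scaling[[cl]] <- c(log = 1, center = mu, scale = sdv)
  }
  for (cl in clin_cols) {
    x <- cohort[[cl]]
    mu <- mean(x, na.rm = TRUE); sdv <- sd(x, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) stopf("zero variance in '%s'", cl)
    cohort[[cl]] <- (x - mu) / sdv
    scaling[[cl]] <- c(log = 0, center = mu, scale = sdv)
  }
  attr(cohort, "prepared") <- TRUE
  attr(cohort, "scaling") <- scaling
  cohort
}

check_outcome <- function(cohort) {
  if (!"af" %in% names(cohort)) stopf("cohort has no 'af' outcome column")
  af <- cohort$af[!is.na(cohort$af)]
  if (!all(af %in% c(0, 1))) stopf("'af' must be binary 0/1")
  if (length(unique(af)) < 2L) stopf("outcome has a single class; cannot fit")
  invisible(TRUE)
}

logistic_fit_table <- function(fit, n) {
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(0.975)
  keep <- names(est) != "(Intercept)"
  data.frame(
    variable = names(est)[keep],
    estimate = unname(est[keep]),
    se = unname(se[keep]),
    or = exp(unname(est[keep])),
    ci_lower = exp(unname(est[keep] - z * se[keep])),
    ci_upper = exp(unname(est[keep] + z * se[keep])),
    p = unname(2 * pnorm(-abs(est[keep] / se[keep]))),
    n = rep(n, sum(keep)),
    stringsAsFactors = FALSE
  )
}

check_separation <- function(fit, variables) {
  est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  bad <- names(est)[is.na(est) | abs(est) > 15 | se > 100]
  bad <- setdiff(bad, "(Intercept)")
  if (length(bad)) {
    stopf("logistic fit did not converge (likely complete separation) for: %s",
          paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Univariate logistic regression of AF on one variable
#'
#' Maximum-likelihood logistic fit of the binary AF outcome on a single
#' prepared variable, with Wald 95% confidence interval and p-value.
#'
#' @param cohort a prepared cohort (see [prepare_features()]).
#' @param variable column name to model.
#' @return One-row data.frame: `variable`, `estimate`, `se`, `or`,
#'   `ci_lower`, `ci_upper`, `p`, `n`.
#' @export
fit_univariate <- function(cohort, variable) {
  check_outcome(cohort)
  if (!variable %in% names(cohort)) stopf("no column '%s'", variable)
  dat <- cohort[stats::complete.cases(cohort[, c("af", variable)]),
                c("af", variable)]
  fit <- suppressWarnings(
    glm(stats::reformulate(variable, response = "af"),
        family = binomial(), data = dat))
  check_separation(fit, variable)
  logistic_fit_table(fit, nrow(dat))
}

#' Multivariate logistic regression of AF on several variables
#'
#' Joint maximum-likelihood logistic fit. The default variable set is the
#' five-descriptor shape model -- components, lesion volume, sphericity,
#' OBB volume, and lesion/OBB ratio; surface area is deliberately
#' excluded because it is collinear with lesion volume. Rank deficiency
#' of the design matrix is an error naming the collinear columns.
#'
#' @param cohort a prepared cohort.
#' @param variables character vector of predictor columns.
#' @return data.frame with one row per variable (see [fit_univariate()]),
#'   with the fitted `glm` attached as attribute `fit`.
#' @export
fit_multivariate <- function(cohort, variables = .default_shape_model) {
  check_outcome(cohort)
  missing <- setdiff(variables, names(cohort))
  if (length(missing)) stopf("no columns: %s", paste(missing, collapse = ", "))
  dat <- cohort[stats::complete.cases(cohort[, c("af", variables)]),
                c("af", variables), drop = FALSE]
  mm <- stats::model.matrix(stats::reformulate(variables), data = dat)
  qd <- qr(mm)
  if (qd$rank < ncol(mm)) {
    dropped <- colnames(mm)[qd$pivot[(qd$rank + 1):ncol(mm)]]
    stopf("design matrix is rank deficient; collinear columns: %s",
          paste(dropped, collapse = ", "))
  }
  fit <- suppressWarnings(
    glm(stats::reformulate(variables, response = "af"),
        family = binomial(), data = dat))
  check_separation(fit, variables)
  out <- logistic_fit_table(fit, nrow(dat))
  attr(out, "fit") <- fit
  out
}

#' Backward stepwise elimination at a fixed significance level
#'
#' Starting from the full multivariate model, repeatedly removes the
#' least significant variable whose Wald p-value exceeds `alpha` and
#' refits, until every remaining variable is significant at `alpha` (or
#' none remain). Ties in the maximal p-value are broken by input variable
#' order, making the procedure deterministic.
#'
#' @param cohort a prepared cohort.
#' @param variables starting variable set.
#' @param alpha significance level for retention (default 0.05).
#' @return data.frame of the final model (empty with attribute
#'   `intercept_only = TRUE` if everything was eliminated); attribute
#'   `trace` records each removal step with its p-value.
#' @export
stepwise_eliminate <- function(cohort, variables = .default_shape_model,
                               alpha = 0.05) {
  current <- variables
  trace <- data.frame(step = integer(), removed = character(),
                      p = numeric(), stringsAsFactors = FALSE)
  step_i <- 0L
  final <- NULL
  while (length(current)) {
    final <- fit_multivariate(cohort, current)
    worst <- which(final$p == max(final$p))[1]  # first index: input-order ties
    if (final$p[worst] <= alpha) break
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(step = step_i,
                                     removed = final$variable[worst],
                                     p = final$p[worst],
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, final$variable[worst])
    final <- NULL
  }
  if (is.null(final)) {
    final <- logistic_fit_table(
      suppressWarnings(glm(af ~ 1, family = binomial(), data = cohort)),
      sum(!is.na(cohort$af)))
    attr(final, "intercept_only") <- TRUE
  }
  attr(final, "trace") <- trace
  final
}

#' Group comparison between AF and non-AF subjects
#'
#' Continuous variables are compared with the two-sided Mann-Whitney test
#' (normal approximation with tie correction) and summarized as median
#' (IQR) per group; binary variables with the chi-squared statistic whose
#' p-value is obtained by Monte-Carlo simulation of tables with fixed
#' margins, p = (1 + #{simulated chi^2 >= observed}) / (1 + replicates).
#'
#' @param cohort cohort data.frame with `af` and feature columns (raw
#'   scale; this function does not require [prepare_features()]).
#' @param continuous,binary columns to compare; defaults cover the
#'   clinical and shape variables present.
#' @param mc_replicates Monte-Carlo replicates for the chi-squared test.
#' @param seed RNG seed for the Monte-Carlo p-values.
#' @return data.frame with one row per variable: group summaries, test
#'   name, p-value, group sizes.
#' @export
compare_groups <- function(cohort,
                           continuous = intersect(c(.clinical_continuous,
                                                    .shape_features),
                                                  names(cohort)),
                           binary = intersect(.binary_features, names(cohort)),
                           mc_replicates = 10000, seed = 1) {
  check_outcome(cohort)
  g0 <- cohort[cohort$af == 0, , drop = FALSE]
  g1 <- cohort[cohort$af == 1, , drop = FALSE]
  if (nrow(g0) == 0 || nrow(g1) == 0) stopf("both AF groups must be non-empty")

  med_iqr <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3])
  }
  n_pct <- function(x) sprintf("%d (%.0f%%)", sum(x == 1, na.rm = TRUE),
                               100 * mean(x == 1, na.rm = TRUE))

  rows <- list()
  for (cl in continuous) {
    wt <- suppressWarnings(
      wilcox.test(g0[[cl]], g1[[cl]], exact = FALSE, correct = TRUE))
    rows[[cl]] <- data.frame(
      variable = cl, type = "continuous",
      no_af = med_iqr(g0[[cl]]), af = med_iqr(g1[[cl]]),
      test = "Mann-Whitney", statistic = unname(wt$statistic),
      p = wt$p.value, n_no_af = sum(!is.na(g0[[cl]])),
      n_af = sum(!is.na(g1[[cl]])), stringsAsFactors = FALSE)
  }
  p_b <- with_rng_seed(seed, {
    lapply(binary, function(cl) {
      tab <- table(factor(cohort$af, c(0, 1)), factor(cohort[[cl]], c(0, 1)))
      suppressWarnings(
        chisq.test(tab, simulate.p.value = TRUE, B = mc_replicates))
    })
  })
  names(p_b) <- binary
  for (cl in binary) {
    ct <- p_b[[cl]]
    rows[[cl]] <- data.frame(
      variable = cl, type = "binary",
      no_af = n_pct(g0[[cl]]), af = n_pct(g1[[cl]]),
      test = "chi-squared (Monte Carlo)", statistic = unname(ct$statistic),
      p = ct$p.value, n_no_af = sum(!is.na(g0[[cl]])),
      n_af = sum(!is.na(g1[[cl]])), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
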