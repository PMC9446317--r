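sim_prepared <- function(n, beta = c(obb_volume_ml = log(2)), seed = 1, ...) {
  prepare_features(simulate_cohort(cohort_sim_config(n, beta = beta,
                                                     seed = seed, ...)))
}

test_that("prepared continuous columns are exact z-scores", {
  prep <- sim_prepared(500, seed = 3)
  for (cl in c("age", "nihss", "volume_ml", "obb_volume_ml", "sphericity")) {
    expect_lt(abs(mean(prep[[cl]])), 1e-9)
    expect_lt(abs(sd(prep[[cl]]) - 1), 1e-9)
  }
  expect_true(all(prep$female %in% 0:1))      # binaries untouched
  expect_true(all(prep$cortical_involved %in% 0:1))
})

test_that("feature preparation is invariant to rescaling a shape column", {
  coh <- simulate_cohort(cohort_sim_config(300, seed = 5))
  coh2 <- coh
  coh2$obb_volume_ml <- coh2$obb_volume_ml * 2  # constant shift in log space
  expect_equal(prepare_features(coh)$obb_volume_ml,
               prepare_features(coh2)$obb_volume_ml, tolerance = 1e-12)
})

test_that("degenerate feature columns are rejected", {
  coh <- simulate_cohort(cohort_sim_config(100, seed = 7))
  coh$volume_ml <- 1.5
  expect_error(prepare_features(coh), "zero variance")
  coh$volume_ml <- c(-1, rep(1, 99))
  expect_error(prepare_features(coh), "non-positive")
})

test_that("perfectly balanced data gives an odds ratio of exactly 1", {
  dat <- data.frame(af = rep(c(0, 1, 0, 1), 25),
                    x = rep(c(-1, -1, 1, 1), 25))
  fit <- fit_univariate(dat, "x")
  expect_equal(fit$or, 1, tolerance = 1e-9)
})

test_that("univariate fit is consistent at large n", {
  prep <- sim_prepared(5000, beta = c(obb_volume_ml = log(2)), seed = 11)
  fit <- fit_univariate(prep, "obb_volume_ml")
  expect_gt(fit$or, 1.85)
  expect_lt(fit$or, 2.15)
  expect_true(fit$ci_lower < fit$or && fit$or < fit$ci_upper)
  expect_equal(fit$or, exp(fit$estimate))
})

test_that("complete separation raises an error naming the variable", {
  dat <- data.frame(af = rep(0:1, each = 30), sep_var = rep(c(0, 5), each = 30))
  expect_error(fit_univariate(dat, "sep_var"), "sep_var")
})

test_that("null-effect Wald intervals achieve nominal coverage", {
  n_seeds <- 200
  covered <- 0L
  for (seed in seq_len(n_seeds)) {
    prep <- sim_prepared(500, beta = c(age = log(2)), seed = seed)
    fit <- fit_univariate(prep, "volume_ml")  # true null variable
    if (fit$ci_lower <= 1 && 1 <= fit$ci_upper) covered <- covered + 1L
  }
  expect_gte(covered / n_seeds, 0.91)
  expect_lte(covered / n_seeds, 0.99)
})

test_that("multivariate default shape set excludes surface area", {
  prep <- sim_prepared(1500, seed = 13)
  fit <- fit_multivariate(prep)
  expect_setequal(fit$variable,
                  c("n_components", "volume_ml", "sphericity",
                    "obb_volume_ml", "lesion_obb_ratio"))
  expect_false("surface_area_mm2" %in% fit$variable)
})

test_that("a duplicated column triggers a rank-deficiency error", {
  prep <- sim_prepared(300, seed = 17)
  prep$obb_copy <- prep$obb_volume_ml
  expect_error(fit_multivariate(prep, c("obb_volume_ml", "obb_copy")),
               "rank deficient")
})

test_that("multivariate coefficients cover their own truth jointly", {
  # data simulated from the fitted model family: each true OR should fall
  # inside its Wald 95% CI in roughly 95% of repetitions
  beta <- c(age = log(2.13), female = log(2.45), obb_volume_ml = log(1.72))
  n_seeds <- 60
  inside <- matrix(FALSE, n_seeds, 3)
  for (seed in seq_len(n_seeds)) {
    prep <- sim_prepared(2000, beta = beta, seed = seed + 400)
    fit <- fit_multivariate(prep, c("age", "female", "obb_volume_ml"))
    fit <- fit[match(names(beta), fit$variable), ]
    inside[seed, ] <- fit$ci_lower <= exp(beta) & exp(beta) <= fit$ci_upper
  }
  for (j in 1:3) expect_gte(mean(inside[, j]), 0.85)
})

test_that("stepwise keeps a fully significant model untouched", {
  beta <- c(age = log(3), female = log(3), obb_volume_ml = log(2.5))
  prep <- sim_prepared(4000, beta = beta, seed = 19)
  sw <- stepwise_eliminate(prep, c("age", "female", "obb_volume_ml"))
  expect_setequal(sw$variable, c("age", "female", "obb_volume_ml"))
  expect_equal(nrow(attr(sw, "trace")), 0)
})

test_that("a pure-noise variable is eliminated first in most runs", {
  beta <- c(age = log(3), obb_volume_ml = log(2.5))
  first_out <- vapply(1:40, function(seed) {
    prep <- sim_prepared(1000, beta = beta, seed = seed + 900)
    sw <- stepwise_eliminate(prep, c("age", "obb_volume_ml", "sphericity"))
    tr <- attr(sw, "trace")
    if (nrow(tr)) tr$removed[1] else ""
  }, character(1))
  expect_gte(mean(first_out == "sphericity"), 0.9)
})

test_that("stepwise trace is sound: removals above alpha, survivors below", {
  prep <- sim_prepared(800, beta = c(age = log(2)), seed = 23)
  vars <- c("age", "female", "n_components", "volume_ml", "sphericity",
            "obb_volume_ml", "lesion_obb_ratio")
  sw <- stepwise_eliminate(prep, vars, alpha = 0.05)
  tr <- attr(sw, "trace")
  expect_true(all(tr$p > 0.05))
  if (nrow(sw)) expect_true(all(sw$p <= 0.05))
  expect_setequal(c(sw$variable, tr$removed), vars)
})

test_that("everything-null stepwise can end intercept-only", {
  prep <- sim_prepared(200, beta = numeric(0), seed = 31)
  vars <- c("volume_ml", "sphericity")
  sw <- stepwise_eliminate(prep, vars, alpha = 1e-6)
  expect_true(isTRUE(attr(sw, "intercept_only")))
  expect_equal(nrow(sw), 0)
})

test_that("identical groups give the symmetric Mann-Whitney statistic", {
  x <- rep(c(1.2, 3.4, 5.6, 7.8), 10)
  dat <- data.frame(af = rep(0:1, each = 40), volume_ml = c(x, x),
                    age = c(x, x))
  cg <- compare_groups(dat, continuous = c("age", "volume_ml"),
                       binary = character(0))
  expect_equal(unname(cg$statistic), rep(40 * 40 / 2, 2))
  expect_true(all(cg$p > 0.99))
})

test_that("Monte-Carlo chi-squared p matches exhaustive enumeration", {
  tabs <- list(matrix(c(8, 2, 3, 9), 2), matrix(c(5, 5, 6, 4), 2),
               matrix(c(10, 1, 2, 12), 2), matrix(c(4, 8, 9, 3), 2))
  for (tb in tabs) {
    exact <- exact_chisq_p_2x2(tb)
    dat <- data.frame(
      af = rep(c(0, 0, 1, 1), times = as.vector(tb)),
      bilateral = rep(c(0, 1, 0, 1), times = as.vector(tb)))
    B <- 20000
    cg <- compare_groups(dat, continuous = character(0),
                         binary = "bilateral", mc_replicates = B, seed = 7)
    se <- sqrt(exact * (1 - exact) / B)
    expect_lt(abs(cg$p - exact), 3 * se + 2 / B)
  }
})

test_that("Monte-Carlo p-values are reproducible under a fixed seed", {
  coh <- simulate_cohort(cohort_sim_config(300, seed = 37))
  a <- compare_groups(coh, seed = 5)
  b <- compare_groups(coh, seed = 5)
  expect_identical(a, b)
})

test_that("a one-SD shift is detected with overwhelming power", {
  pvals <- vapply(1:20, function(seed) {
    set.seed(seed + 5000)
    dat <- data.frame(af = rep(0:1, each = 200),
                      age = c(rnorm(200), rnorm(200, 1)))
    compare_groups(dat, continuous = "age", binary = character(0))$p
  }, numeric(1))
  expect_true(all(pvals < 0.001))
})

test_that("large-sample coefficient recovery is nearly unbiased", {
  beta <- c(age = log(2.13), female = log(2.45), obb_volume_ml = log(1.72))
  ests <- sapply(1:12, function(seed) {
    prep <- sim_prepared(5000, beta = beta, seed = seed + 700)
    fit <- fit_multivariate(prep, names(beta))
    fit$estimate[match(names(beta), fit$variable)]
  })
  bias <- rowMeans(ests) - beta
  expect_true(all(abs(bias) < 0.05))
})
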