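# REML model development: degenerate limits, deviance ordering, Wald
# identities, invariances, and the random-structure tests.

test_that("REML with zero group variance matches ordinary least squares", {
  # degenerate limit: noise with its sheep/season/year group means
  # projected out, so every variance component sits at the boundary and
  # the generalized-least-squares solution is exactly OLS
  d <- test_dataset(11)
  set.seed(111)
  eps <- rnorm(nrow(d), 0, 0.9)
  eps <- resid(lm(eps ~ factor(d$sheep_id) + factor(d$season) +
                    factor(d$year)))
  d$de <- -0.527 + 18.552 * d$dmd + eps
  mixed <- fit_reml(d, "DE", "DMD")
  expect_equal(sum(mixed$varcomp$variance), 0, tolerance = 1e-8)
  ols <- fit_reml(d, "DE", "DMD", random = character(0))
  expect_equal(mixed$coefficients$estimate, ols$coefficients$estimate,
               tolerance = 1e-6)
  # at zero variance components the SEs agree with the classical OLS SEs
  expect_equal(mixed$coefficients$se, ols$coefficients$se,
               tolerance = 1e-6)
  # and the deviances agree across the mixed/OLS code paths
  expect_equal(mixed$deviance, ols$deviance, tolerance = 1e-6)
})

test_that("full-model REML deviance never exceeds a nested reduction", {
  d <- test_dataset(31)
  subsets <- list(c("sheep", "season", "year"), c("sheep", "year"),
                  c("season"), character(0))
  fits <- lapply(subsets, function(r) fit_reml(d, "ME", "GED", random = r))
  full <- fits[[1]]
  for (f in fits[-1]) {
    expect_lte(full$deviance, f$deviance + 1e-6)
    cmp <- compare_random_structures(full, f)
    expect_gte(cmp$p_value, 0)
    expect_equal(cmp$df, 3 - length(f$random))
  }
  # identical models: zero change, p = 1
  same <- compare_random_structures(full, fits[[1]])
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_random_structures(
    full, fit_reml(d, "ME", "DMD", random = "sheep")), "same fixed")
})

test_that("R^2 is the squared response-fitted correlation with its limits", {
  d <- test_dataset(12)
  # saturated: response exactly collinear with a predictor
  d$me <- 2 + 3 * d$ged
  sat <- fit_reml(d, "ME", "GED", random = character(0))
  expect_equal(sat$r2, 1)
  expect_equal(sat$coefficients$estimate, c(2, 3), tolerance = 1e-9)
  # constant fitted values
  d2 <- test_dataset(12)
  flat <- fit_reml(d2, "ME", character(0), random = character(0))
  expect_equal(flat$r2, 0)
  # general case equals cor(y, fitted)^2 computed by hand
  f <- fit_reml(d2, "ME", c("DMD", "GE"), random = character(0))
  X <- cbind(1, d2$dmd, d2$ge)
  expect_equal(f$r2, cor(d2$me, X %*% f$coefficients$estimate)[1]^2)
})

test_that("estimates are invariant to record and predictor order", {
  d <- test_dataset(13)
  f1 <- fit_reml(d, "ME", c("DMD", "N", "GE"))
  shuffled <- d[rev(seq_len(nrow(d))), ]
  f2 <- fit_reml(shuffled, "ME", c("DMD", "N", "GE"))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-5)
  f3 <- fit_reml(d, "ME", c("GE", "DMD", "N"))
  expect_equal(
    f1$coefficients$estimate[match(c("N", "GE"), f1$coefficients$term)],
    f3$coefficients$estimate[match(c("N", "GE"), f3$coefficients$term)],
    tolerance = 1e-5)
})

test_that("rank-deficient designs are refused naming the collinear term", {
  d <- test_dataset(14)
  d$cp <- 6.25 * d$n  # exact collinearity with N
  expect_error(fit_reml(d, "ME", c("N", "CP"), random = character(0)),
               "collinear.*CP")
  expect_error(fit_reml(d, "DE", c("DMD", "DMD")), "unique")
  expect_error(fit_reml(d, "DE", "DE"), "Response cannot")
})

test_that("Wald statistic is (estimate/SE)^2 against chi-squared(1)", {
  d <- test_dataset(15)
  f <- fit_reml(d, "ME", c("GED", "N"), random = character(0))
  w <- wald_test(f, "GED")
  i <- match("GED", f$coefficients$term)
  expect_equal(w$statistic,
               (f$coefficients$estimate[i] / f$coefficients$se[i])^2)
  expect_equal(w$p_value,
               pchisq(w$statistic, 1, lower.tail = FALSE))
  # normal-quantile identity: estimate at 1.96 SE gives p ~ 0.05
  expect_equal(pchisq(1.96^2, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
  expect_error(wald_test(f, "NDF"), "not in the fitted model")
})

test_that("equation development drops unsupported random terms to OLS", {
  cfg <- generator_config(seed = 16,
                          random_effects = c(sheep = 0, season = 0,
                                             year = 0))
  eq <- load_builtin_registry("table4")[1, ]  # ME ~ DE
  d <- generate_from_equation(eq, cfg, noise_sd = 0.4)
  dev <- develop_equation(d, "ME", "DE", id = "refit-2i")
  fit <- attr(dev, "fit")
  ols <- fit_reml(d, "ME", "DE", random = character(0))
  # with no true group variance the selected model collapses to OLS
  expect_equal(fit$coefficients$estimate, ols$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(dev$intercept, ols$coefficients$estimate[1],
               tolerance = 1e-6)
  expect_equal(dev$terms[[1]]$coefficient, ols$coefficients$estimate[2],
               tolerance = 1e-6)
  expect_identical(dev$source, "refit")
  expect_error(develop_equation(d[setdiff(names(d), "domd")], "ME", "DOMD"),
               "domd")
})

test_that("noise-free generation refits to the exact generating equation", {
  cfg <- generator_config(seed = 17,
                          random_effects = c(sheep = 0, season = 0,
                                             year = 0))
  eq <- load_builtin_registry("table2")[1, ]
  d <- generate_from_equation(eq, cfg, noise_sd = 0)
  fit <- fit_reml(d, "DE", "DMD", random = character(0))
  expect_equal(fit$coefficients$estimate, c(-0.527, 18.552),
               tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("a large injected season effect is detected by deviance", {
  # power check at the spec's scale, reduced replicate count for the
  # routine suite (the acceptance suite carries the full simulations)
  eq <- load_builtin_registry("table4")[1, ]
  hits <- 0L
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    cfg <- generator_config(seed = 5000 + r,
                            random_effects = c(sheep = 0, season = 1,
                                               year = 0))
    d <- generate_from_equation(eq, cfg, noise_sd = 0.5)
    full <- fit_reml(d, "ME", "DE", random = c("season", "year"))
    red <- fit_reml(d, "ME", "DE", random = "year")
    if (compare_random_structures(full, red)$p_value < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("deviance test of a null random term is conservative", {
  eq <- load_builtin_registry("table4")[1, ]
  rejections <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    cfg <- generator_config(seed = 9000 + r,
                            random_effects = c(sheep = 0, season = 0,
                                               year = 0))
    d <- generate_from_equation(eq, cfg, noise_sd = 0.5)
    full <- fit_reml(d, "ME", "DE", random = "season")
    red <- fit_reml(d, "ME", "DE", random = character(0))
    if (compare_random_structures(full, red)$p_value < 0.05) {
      rejections <- rejections + 1L
    }
  }
  # boundary-at-zero makes the plain chi-squared reference conservative
  expect_lte(rejections / n_rep, 0.10)
})

test_that("model specs extracted from a registry refit its forms", {
  specs <- model_specs_from_registry("table4")
  expect_equal(specs$id, c("2i", "2j", "2k", "2l", "2m"))
  expect_equal(specs$predictors[[5]], c("DE", "Ash", "ADF"))
  expect_true(all(specs$response == "ME"))
})
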