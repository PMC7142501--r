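# Validation statistics and the report harness.

test_that("MSPE is the mean squared difference", {
  expect_equal(mspe(c(1, 2), c(0, 0)), 2.5)
  expect_equal(mspe(c(5, 7, 9), c(5, 7, 9)), 0)
  expect_equal(mspe(3, 1), 4)
  expect_error(mspe(1:3, 1:2), "equal length")
})

test_that("MPE is sqrt(MSPE)/mean(A), scale invariant, guarded", {
  # MSPE = 1 and mean(A) = 10 gives 0.1
  expect_equal(mpe(c(11, 9), c(10, 10)), 0.1)
  expect_equal(mpe(c(4, 4), c(4, 4)), 0)
  p <- c(10.2, 11.4, 9.1); a <- c(10, 11, 9.5)
  for (c_ in c(0.01, 1, 42)) {
    expect_equal(mpe(c_ * p, c_ * a), mpe(p, a))
  }
  expect_error(mpe(c(1, 2), c(-3, 1)), "positive mean")
})

test_that("MSPE decomposes into squared bias plus residual variance", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    p <- rnorm(n, 10, 2); a <- rnorm(n, 9.5, 2)
    d <- p - a
    expect_equal(mspe(p, a), mean(d)^2 + mean((d - mean(d))^2),
                 tolerance = 1e-12)
  }
})

test_that("Lin's concordance matches hand computation and its bounds", {
  expect_equal(lins_ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(lins_ccc(c(2, 3, 4), c(1, 2, 3)), 4 / 7)
  a <- c(1, 2, 3, 4)
  expect_lt(lins_ccc(mean(a) - (a - mean(a)), a), 0)
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    p <- rnorm(n); a2 <- rnorm(n)
    rc <- lins_ccc(p, a2)
    expect_lte(abs(rc), abs(cor(p, a2)) + 1e-12)
    expect_lte(abs(rc), 1)
    # equality exactly when means and variances agree: standardise both
    # to the same moments and check
    ps <- (p - mean(p)) / sd(p); as_ <- (a2 - mean(a2)) / sd(a2)
    expect_equal(lins_ccc(ps, as_), cor(ps, as_), tolerance = 1e-12)
  }
  expect_error(lins_ccc(c(1, 1), c(1, 1)), "undefined")
})

test_that("residual summaries are of predicted minus actual", {
  expect_equal(unlist(residual_summary(c(1, 2), c(1, 2))),
               c(mean = 0, sd = 0, min = 0, max = 0))
  rs <- residual_summary(c(0, 2), c(1, 1))
  expect_equal(rs$mean, 0)
  expect_equal(rs$min, -1)
  expect_equal(rs$max, 1)
})

test_that("the stratified split is 44/22, per-trial 4/2, deterministic", {
  d <- test_dataset()
  sp <- split_trial_data(d, seed = 42)
  expect_equal(nrow(sp$train), 44)
  expect_equal(nrow(sp$test), 22)
  per_trial <- table(sp$train$trial_id)
  expect_true(all(per_trial == 4))
  expect_true(all(table(sp$test$trial_id) == 2))
  sp2 <- split_trial_data(d, seed = 42)
  expect_identical(sp, sp2)
  sp3 <- split_trial_data(d, seed = 43)
  expect_false(identical(sp$train$sheep_id, sp3$train$sheep_id) &&
                 identical(sp$train$trial_id, sp3$train$trial_id))
})

test_that("splits partition the data for any seed", {
  d <- test_dataset()
  key <- function(x) paste(x$trial_id, x$sheep_id)
  for (s in c(1, 7, 123, 99991)) {
    sp <- split_trial_data(d, seed = s)
    expect_equal(sort(c(key(sp$train), key(sp$test))), sort(key(d)))
    expect_length(intersect(key(sp$train), key(sp$test)), 0)
  }
  expect_error(split_trial_data(d, fraction = 1.2), "between 0 and 1")
  one_sheep <- d[!duplicated(d$trial_id), ]
  expect_error(split_trial_data(one_sheep, seed = 1), "at least 2")
})

test_that("validating a perfect or offset equation gives known reports", {
  d <- test_dataset(21)
  # a perfect equation: response regenerated from the equation, no noise
  eq <- load_builtin_registry("table2")[1, ]
  dp <- generate_from_equation(eq, generator_config(
    seed = 21, random_effects = c(sheep = 0, season = 0, year = 0)),
    noise_sd = 0)
  rep_perfect <- validate_equations(dp, eq)
  expect_equal(rep_perfect$mpe, 0, tolerance = 1e-12)
  expect_equal(rep_perfect$rc, 1, tolerance = 1e-9)
  expect_equal(rep_perfect$resid_sd, 0, tolerance = 1e-9)

  # constant offset +1 on a response with mean 10: MPE 0.1, residual mean 1
  d10 <- tibble::tibble(me = rep(10, 8) + seq(-0.7, 0.7, length.out = 8),
                        de = rep(10, 8) + seq(-0.7, 0.7, length.out = 8))
  d10$me <- d10$me - mean(d10$me) + 10
  d10$de <- d10$me
  off <- energy_equation("off", "ME", 1, list(equation_term("DE", 1)))
  rep_off <- validate_equations(d10, off)
  expect_equal(rep_off$mpe, 0.1, tolerance = 1e-12)
  expect_equal(rep_off$resid_mean, 1, tolerance = 1e-12)
  expect_equal(rep_off$resid_sd, 0, tolerance = 1e-12)
})

test_that("benchmarking collects per-equation errors without aborting", {
  d <- test_dataset(22)
  reports <- validate_equations(d, "table8")
  expect_equal(nrow(reports), 13)
  expect_true(all(is.na(reports$error)))
  expect_true(all(reports$rc >= -1 & reports$rc <= 1))
  expect_true(all(abs(reports$rc) <=
                    abs(sqrt(reports$r2)) + 1e-9))
  expect_true(all(reports$resid_min <= reports$resid_mean &
                    reports$resid_mean <= reports$resid_max))
  # drop a needed predictor: only the dependent rows error out
  broken <- validate_equations(d[setdiff(names(d), "domd")], "table8")
  uses_domd <- c("AQ", "AR", "AV", "AX")
  expect_true(all(!is.na(broken$error[broken$equation_id %in% uses_domd])))
  expect_true(all(is.na(broken$error[!broken$equation_id %in% uses_domd])))
  # empty registry gives an empty report
  expect_equal(nrow(validate_equations(d, load_builtin_registry(
    "table8")[0, ])), 0)
})

test_that("published validation rows average to the published MPE means", {
  avg <- average_mpe_by_response(reference_validation("internal"))
  expect_equal(avg$mpe_display[avg$response == "DE"], 0.013)
  expect_equal(avg$mpe_display[avg$response == "ME"], 0.033)
  expect_equal(avg$mpe_display[avg$response == "DE/GE"], 0.015)
  expect_equal(avg$n_equations[avg$response == "ME"], 15)
  one <- average_mpe_by_response(reference_validation("internal")[1, ])
  expect_equal(one$mean_mpe, 0.010)
})

test_that("residual series are exact and plot without fitting", {
  d <- test_dataset(23)
  eq <- load_builtin_registry("table2")[4, ]  # ME ~ DOMD (2a)
  dat <- residual_plot_data(d, eq)
  expect_equal(nrow(dat), nrow(d))
  expect_equal(dat$residual, dat$predicted - d$me)
  off <- energy_equation("off", "ME", 1, list(equation_term("DE", 1)))
  d2 <- d; d2$me <- d2$de
  expect_equal(unique(round(residual_plot_data(d2, off)$residual, 12)), 1)
  p <- plot_residuals(d, eq)
  expect_s3_class(p, "ggplot")
})
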