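# Synthetic-trial generator: design, determinism, energy balance,
# marginal plausibility.

test_that("the default design is 11 trials x 6 sheep with valid records", {
  d <- generate_trial_data(generator_config(seed = 5))
  expect_equal(nrow(d), 66)
  expect_equal(length(unique(d$trial_id)), 11)
  expect_true(all(table(d$trial_id) == 6))
  expect_equal(sort(unique(d$season)), sort(c("june", "august", "december")))
  expect_equal(nrow(validate_records(d)), 0)
})

test_that("generation is deterministic given the seed, byte for byte", {
  cfg <- generator_config(seed = 77)
  d1 <- generate_trial_data(cfg)
  d2 <- generate_trial_data(cfg)
  expect_identical(d1, d2)
  f1 <- tempfile(); f2 <- tempfile()
  on.exit(unlink(c(f1, f2)))
  write_trial_records(d1, f1)
  write_trial_records(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- generate_trial_data(generator_config(seed = 78))
  expect_false(identical(d1$de, d3$de))
  # the generator restores the caller's RNG state
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_trial_data(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("the energy balance is exact and ME is always below DE", {
  d <- generate_trial_data(generator_config(seed = 6), keep_balance = TRUE)
  expect_true(all(d$me < d$de))
  expect_true(all(d$me > 0))
  expect_equal(d$ge, d$fecal_energy + d$urine_energy + d$methane_energy +
                 d$me, tolerance = 1e-9)
  expect_equal(d$de, d$ge - d$fecal_energy, tolerance = 1e-12)
  # with measurement noise off, the recorded GED is exactly DE/GE and
  # DOMD is exactly OMD x (1 - ash)
  clean <- generate_trial_data(generator_config(seed = 6,
                                                ged_noise_sd = 0,
                                                domd_noise_sd = 0))
  expect_equal(clean$ged, clean$de / clean$ge, tolerance = 1e-12)
  expect_equal(clean$domd, clean$omd * (1 - clean$ash), tolerance = 1e-12)
  expect_equal(clean$de_ge, clean$ged, tolerance = 1e-12)
})

test_that("default marginals stay within the reference ranges widened 20%", {
  d <- generate_trial_data(generator_config(seed = 8))
  s <- summarize_dataset(d)
  rng <- ref_ranges()
  for (v in names(rng)) {
    row <- s[s$variable == v, ]
    expect_gte(row$min, 0.8 * rng[[v]][["min"]])
    expect_lte(row$max, 1.2 * rng[[v]][["max"]])
  }
})

test_that("seasonal profiles encode the summer-winter quality gradient", {
  pr <- seasonal_profiles("qtp_default")
  get <- function(v, s) pr[[s]][pr$variable == v]
  expect_lt(get("dmd", "december"), get("dmd", "august"))
  expect_lt(get("ged", "december"), get("ged", "june"))
  expect_gt(get("ndf", "december"), get("ndf", "june"))
  expect_gt(get("n", "june"), get("n", "december"))
  # profile means lie inside the reference min-max (file-layer units)
  ref <- reference_summary("printed")
  for (v in pr$variable) {
    lo <- ref$min[ref$variable == v]; hi <- ref$max[ref$variable == v]
    for (s in c("june", "august", "december")) {
      expect_gte(get(v, s), lo)
      expect_lte(get(v, s), hi)
    }
  }
  # the +-2 SD envelope spans the published fresh-DM extremes [323, 809]
  dm <- pr[pr$variable == "dm_fresh", ]
  spread <- 2 * (dm$trial_sd + dm$record_sd)
  expect_lte(min(dm$june, dm$august, dm$december) - spread, 323)
  expect_gte(max(dm$june, dm$august, dm$december) + spread, 809)
  expect_error(seasonal_profiles("alps"), "Unknown preset")
})

test_that("digestibility tracks the quality gradient in generated data", {
  d <- generate_trial_data(generator_config(seed = 9))
  expect_gt(cor(d$dmd, d$n), 0.5)
  expect_lt(cor(d$dmd, d$ndf), -0.5)
  expect_gt(cor(d$me, d$ged), 0.8)
})

test_that("dataset means converge to the configured seasonal means", {
  # Monte-Carlo check over seeds: the grand mean of each variable
  # approaches its design-weighted profile mean within 2 MC SEs
  pr <- seasonal_profiles("qtp_default")
  w <- c(june = 2, august = 5, december = 4) / 11
  target <- function(v) {
    row <- pr[pr$variable == v, ]
    w[["june"]] * row$june + w[["august"]] * row$august +
      w[["december"]] * row$december
  }
  n_seeds <- 50
  vars <- c("dmd", "ged", "omd")
  means <- sapply(seq_len(n_seeds), function(s) {
    d <- generate_trial_data(generator_config(seed = 3000 + s))
    vapply(vars, function(v) mean(d[[v]]), numeric(1))
  })
  for (v in vars) {
    mc_mean <- mean(means[v, ])
    mc_se <- sd(means[v, ]) / sqrt(n_seeds)
    # truncation makes the draw slightly non-normal; allow a small bias
    # floor alongside the MC error
    expect_lt(abs(mc_mean - target(v)), 2 * mc_se + 0.004)
  }
})

test_that("infeasible configurations are refused before sampling", {
  expect_error(generator_config(urine_fraction = c(0.6, 0),
                                methane_fraction = c(0.5, 0)),
               "sum below 1")
  expect_error(generator_config(sheep_sd = -1), "non-negative")
  pr <- seasonal_profiles("qtp_default")
  pr$june[pr$variable == "dmd"] <- 1.4
  expect_error(generator_config(profiles = pr), "Infeasible")
  expect_error(generator_config(n_trials = 0), "at least one")
})

test_that("generate_from_equation injects exactly the requested structure", {
  eq <- load_builtin_registry("table4")[1, ]  # ME ~ DE
  cfg0 <- generator_config(seed = 12, random_effects = c(
    sheep = 0, season = 0, year = 0))
  d0 <- generate_from_equation(eq, cfg0, noise_sd = 0)
  expect_equal(d0$me, -1.38 + 0.964 * d0$de, tolerance = 1e-12)
  # with a season effect, season explains extra response variance
  cfg1 <- generator_config(seed = 12, random_effects = c(
    sheep = 0, season = 4, year = 0))
  d1 <- generate_from_equation(eq, cfg1, noise_sd = 0)
  resid0 <- d0$me - (-1.38 + 0.964 * d0$de)
  resid1 <- d1$me - (-1.38 + 0.964 * d1$de)
  expect_equal(sd(resid0), 0, tolerance = 1e-12)
  expect_gt(sd(resid1), 0.5)
  expect_equal(length(unique(round(resid1, 9))), 3)  # one shift per season
  expect_error(generate_from_equation(load_builtin_registry("table8"),
                                      cfg0), "single equation")
})
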