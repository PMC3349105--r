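test_that("generated tables round-trip through the dataset module", {
  tabs <- simulate_tables(simulation_config(seed = 21))
  dir <- withr::local_tempdir()
  write_tables(tabs, dir)
  back <- load_tables(dir)
  expect_s3_class(back, "qsar_tables")
  expect_equal(back$activities, tabs$activities, tolerance = 1e-12)
  expect_equal(as.data.frame(back$retention$DS_A),
               as.data.frame(tabs$retention$DS_A), tolerance = 1e-12)
  expect_equal(back$descriptors$HD, tabs$descriptors$HD)
})

test_that("generation is reproducible from the seed and leaves the RNG alone", {
  cfg <- simulation_config(seed = 33)
  a <- simulate_tables(cfg)
  withr::with_seed(1, runif(1))
  b <- simulate_tables(cfg)
  expect_identical(a$activities, b$activities)
  expect_identical(a$retention, b$retention)

  before <- withr::with_seed(5, rnorm(3))
  withr::with_seed(5, {
    invisible(simulate_tables(cfg))
    after <- rnorm(3)
  })
  expect_identical(before, after)
})

test_that("requested predictor correlation is realized at large n", {
  cfg <- simulation_config(n_compounds = 1000, correlation = 0.48, seed = 9,
                           missing_rate = c(pKi = 0, pD2 = 0, pA2 = 0))
  tabs <- simulate_tables(cfg)
  feats <- derive_features(tabs$retention$DS_A)
  r <- cor(feats[["C-S4"]], feats[["C-S5"]])
  expect_near(r, 0.48, 0.1)
})

test_that("noiseless synthetic data recover the truth through the whole pipeline", {
  cfg <- simulation_config(noise_sd = 0, seed = 14)
  tabs <- simulate_tables(cfg)
  d <- assemble_dataset(tabs, "pD2", names(cfg$terms), "DS_A")
  fit <- fit_qsar(d)
  expect_equal(fit$coefficients$estimate, cfg$true_beta, tolerance = 1e-8)
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)
  expect_equal(loo_crossval(d)$Q2, 1, tolerance = 1e-8)
})

test_that("missing-activity bookkeeping matches the assembled row count", {
  cfg <- simulation_config(missing_rate = c(pKi = 0.05, pD2 = 0.3, pA2 = 0.2),
                           seed = 55)
  tabs <- simulate_tables(cfg)
  non_missing <- sum(!is.na(tabs$activities$pD2))
  d <- assemble_dataset(tabs, "pD2", names(cfg$terms), "DS_A")
  expect_equal(nrow(d), non_missing)
  # n = 20, rate 0.3: essentially all draws leave 9..20 non-missing
  expect_gte(non_missing, qbinom(0.0005, 20, 0.7))
})

test_that("a study-like configuration lands in the study's fit-quality range", {
  # 13 compounds, two RM-difference predictors, published-scale
  # coefficients and noise: most realizations should fit like the study
  cfg0 <- simulation_config(n_compounds = 13, true_beta = c(7.7, -16, 8),
                            noise_sd = 0.37,
                            missing_rate = c(pKi = 0, pD2 = 0, pA2 = 0))
  in_range <- vapply(1:200, function(r) {
    cfg <- cfg0; cfg$seed <- 1000 + r
    d <- assemble_dataset(simulate_tables(cfg), "pD2", names(cfg$terms), "DS_A")
    r2 <- fit_qsar(d)$r.squared
    r2 > 0.6 && r2 < 0.95
  }, logical(1))
  expect_gte(mean(in_range), 0.9)
})

test_that("recovery_experiment is unbiased at zero noise and deterministic", {
  rec0 <- recovery_experiment(simulation_config(noise_sd = 0, seed = 2), 3)
  expect_equal(rec0$bias, rep(0, 3), tolerance = 1e-8)
  expect_equal(attr(rec0, "mean_Q2"), 1, tolerance = 1e-8)

  rec_a <- recovery_experiment(simulation_config(seed = 8), 1)
  rec_b <- recovery_experiment(simulation_config(seed = 8), 1)
  expect_identical(as.data.frame(rec_a), as.data.frame(rec_b))
  expect_identical(attr(rec_a, "mean_Q2"), attr(rec_b, "mean_Q2"))
})

test_that("predictive power decays monotonically with noise", {
  grid <- c(0, 0.2, 0.4, 0.8)
  mean_q2 <- vapply(grid, function(ns) {
    attr(recovery_experiment(
      simulation_config(noise_sd = ns, seed = 60,
                        missing_rate = c(pKi = 0, pD2 = 0, pA2 = 0)),
      25
    ), "mean_Q2")
  }, numeric(1))
  expect_true(all(diff(mean_q2) < 0))
})

test_that("null coefficients give no predictive power", {
  rec <- recovery_experiment(
    simulation_config(true_beta = c(7.7, 0, 0), noise_sd = 0.37, seed = 90,
                      missing_rate = c(pKi = 0, pD2 = 0, pA2 = 0)),
    50
  )
  expect_lte(attr(rec, "mean_Q2"), 0.05)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(simulation_config(correlation = 1.2), "positive-definite")
  expect_error(simulation_config(noise_sd = -1), "non-negative")
  expect_error(simulation_config(true_beta = c(1, 2)), "intercept plus one")
  expect_error(simulation_config(missing_rate = c(pKi = 1, pD2 = 0, pA2 = 0)),
               "rate in \\[0, 1\\)")
})

test_that("key-value config files reproduce an equivalent configuration", {
  path <- withr::local_tempfile(lines = c(
    "# synthetic study configuration",
    "n_compounds = 16",
    "response = pA2",
    "phase = DS_B",
    "terms = C-S6, logP",
    "locations = 0, 0",
    "scales = 0.05, 1.3",
    "beta = 6.5, 15.6, 0.45",
    "noise_sd = 0.59",
    "missing_pa2 = 0.1",
    "seed = 42"
  ))
  cfg <- read_simulation_config(path)
  expect_equal(cfg$n_compounds, 16L)
  expect_equal(cfg$response, "pA2")
  expect_equal(names(cfg$terms), c("C-S6", "logP"))
  expect_equal(cfg$true_beta, c(6.5, 15.6, 0.45))
  expect_equal(cfg$missing_rate[["pA2"]], 0.1)
  tabs <- simulate_tables(cfg)
  expect_equal(sum(!is.na(tabs$activities$pA2)) +
                 sum(is.na(tabs$activities$pA2)), 16)
})
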