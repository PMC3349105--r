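test_that("fit_qsar agrees with the normal-equations oracle on the study models", {
  for (data in list(eq6_data(), eq5_data(), eq15_data())) {
    fit <- fit_qsar(data)
    oracle <- ols_oracle(data[attr(data, "terms")], data[[attr(data, "response")]])
    expect_equal(fit$coefficients$estimate, unname(oracle$beta), tolerance = 1e-8)
    expect_equal(fit$r.squared, oracle$r2, tolerance = 1e-8)
    expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
  }
})

test_that("fit_qsar recovers exact linear structure", {
  # response identically one predictor
  tabs <- study_tables()
  d <- assemble_dataset(tabs, "pD2", "C-S4", "DS_A")
  d$pD2 <- d[["C-S4"]]
  fit <- fit_qsar(d)
  expect_equal(fit$coefficients$estimate, c(0, 1), tolerance = 1e-10)
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)

  # random 8 x 2 design with known coefficients and zero noise
  withr::with_seed(404, {
    df <- tibble::tibble(
      compound_id = 1:8,
      x1 = rnorm(8), x2 = rnorm(8)
    )
    df$pKi <- 2.5 - 1.25 * df$x1 + 0.75 * df$x2
  })
  d2 <- as_qsar_dataset(df, "pKi", c("x1", "x2"))
  fit2 <- fit_qsar(d2)
  expect_equal(fit2$coefficients$estimate, c(2.5, -1.25, 0.75), tolerance = 1e-10)
  oracle <- ols_oracle(df[c("x1", "x2")], df$pKi)
  expect_equal(fit2$coefficients$estimate, unname(oracle$beta), tolerance = 1e-10)
})

test_that("fit statistics are mutually consistent and within their invariants", {
  fit <- fit_qsar(eq6_data())
  n <- fit$n; p <- fit$p
  expect_equal(fit$statistic,
               (fit$r.squared / p) / ((1 - fit$r.squared) / (n - p - 1)),
               tolerance = 1e-8)
  expect_equal(fit$adj.r.squared,
               1 - (1 - fit$r.squared) * (n - 1) / (n - p - 1),
               tolerance = 1e-8)
  expect_equal(fit$sigma, sqrt(fit$rss / (n - p - 1)), tolerance = 1e-8)
  expect_equal(fit$r, sqrt(fit$r.squared), tolerance = 1e-12)
  expect_equal(fit$p.value, pf(fit$statistic, p, n - p - 1, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_true(fit$r.squared >= 0 && fit$r.squared <= 1)
  expect_lte(fit$adj.r.squared, fit$r.squared)
  expect_lt(abs(sum(residuals(fit$lm))), 1e-9)
  expect_gt(fit$n, fit$p + 1)
})

test_that("degenerate designs are rejected", {
  df <- tibble::tibble(compound_id = 1:6, x1 = rnorm(6))
  df$x2 <- 2 * df$x1
  df$pKi <- rnorm(6)
  expect_error(fit_qsar(as_qsar_dataset(df, "pKi", c("x1", "x2"))),
               "rank deficient")
  tiny <- as_qsar_dataset(df[1:3, ], "pKi", c("x1", "x2"))
  expect_error(fit_qsar(tiny), "too small")
})

test_that("correlation_matrix matches the published agonist-subset entries", {
  cm <- correlation_matrix(eq6_data())
  expect_near(unclass(cm)["C-S4", "pD2"], -0.81, 0.01)
  # the C-S5 column is small in magnitude, so 3-dp RM rounding moves this
  # entry a little more than the last printed digit
  expect_near(unclass(cm)["C-S4", "C-S5"], 0.48, 0.02)
  expect_equal(diag(unclass(cm)), c(`C-S4` = 1, `C-S5` = 1, pD2 = 1))
  expect_true(isSymmetric(unclass(cm)))
  expect_true(all(abs(unclass(cm)) <= 1 + 1e-12))
  expect_equal(attr(cm, "n"), 13)
})

test_that("correlation_matrix is affine-invariant and rejects degenerate columns", {
  d <- eq6_data()
  cm1 <- unclass(correlation_matrix(d))
  d2 <- d
  d2[["C-S4"]] <- 100 * d2[["C-S4"]] - 7
  d2[["pD2"]] <- 0.1 * d2[["pD2"]] + 3
  cm2 <- unclass(correlation_matrix(d2))
  expect_equal(abs(cm2), abs(cm1), tolerance = 1e-12)

  # hand case: exact linearity
  df <- tibble::tibble(compound_id = 1:4, x = 1:4, pKi = c(2, 4, 6, 8))
  cm3 <- correlation_matrix(as_qsar_dataset(df, "pKi", "x"))
  expect_equal(unclass(cm3)["x", "pKi"], 1)

  dz <- d
  dz[["C-S5"]] <- 1
  expect_error(correlation_matrix(dz), "Zero-variance")
})

test_that("collinearity_filter removes the weaker member of a correlated pair", {
  # over the antagonist-activity subset, the DS_B differences C-S4 and
  # C-S6 correlate above the 0.5 cut; C-S6 is the one tied to pA2
  d <- assemble_dataset(study_tables(), "pA2", c("C-S4", "C-S6"), "DS_B")
  r <- cor(d[["C-S4"]], d[["C-S6"]])
  expect_gt(abs(r), 0.5)
  kept <- collinearity_filter(d, c("C-S4", "C-S6"))
  expect_equal(kept, "C-S6")

  # already-admissible candidate sets come back unchanged
  d2 <- eq6_data()
  d2_low <- collinearity_filter(d2, c("C-S4", "C-S5"), threshold = 0.5)
  expect_equal(d2_low, c("C-S4", "C-S5"))
})

test_that("collinearity_filter matches subset enumeration and is threshold-monotone", {
  withr::with_seed(2024, {
    x1 <- rnorm(20)
    df <- tibble::tibble(
      compound_id = 1:20,
      x1 = x1,
      x2 = 0.9 * x1 + sqrt(1 - 0.81) * rnorm(20),
      x3 = rnorm(20)
    )
    df$pKi <- x1 + 0.3 * df$x3 + rnorm(20, sd = 0.5)
  })
  d <- as_qsar_dataset(df, "pKi", c("x1", "x2", "x3"))
  kept <- collinearity_filter(d, c("x1", "x2", "x3"))

  # oracle: enumerate all subsets, keep the admissible ones of maximal
  # size, prefer the one whose members correlate most with the response
  cand <- c("x1", "x2", "x3")
  cm <- abs(cor(as.matrix(df[cand])))
  admissible <- Filter(function(s) {
    length(s) < 2 || max(cm[s, s][upper.tri(cm[s, s])]) <= 0.5
  }, unlist(lapply(seq_along(cand), function(k)
    combn(cand, k, simplify = FALSE)), recursive = FALSE))
  best_size <- max(lengths(admissible))
  expect_equal(length(kept), best_size)
  expect_true(all(abs(cor(as.matrix(df[kept])))[upper.tri(diag(length(kept)))] <= 0.5))
  expect_setequal(kept, c("x1", "x3"))

  # tightening the threshold can only shrink the kept set
  sizes <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1),
                  function(th) length(collinearity_filter(d, cand, threshold = th)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("stepwise_select recovers the published agonist model and stops correctly", {
  d <- eq6_data()
  spec <- stepwise_select(d, c("C-S4", "C-S5"))
  expect_setequal(spec$terms, c("C-S4", "C-S5"))
  expect_equal(spec$status, "ok")

  # single perfectly-correlated candidate: selected, then stop
  d1 <- d
  d1$pD2 <- 3 - 2 * d1[["C-S4"]]
  spec1 <- stepwise_select(d1, c("C-S4", "C-S5"))
  expect_equal(spec1$terms, "C-S4")

  # candidate orthogonal to the response by construction: intercept-only
  df <- tibble::tibble(compound_id = 1:10, x = rep(c(1, -1), 5),
                       pD2 = rep(c(3, 3, 5, 5, 4), 2))
  expect_warning(spec0 <- stepwise_select(as_qsar_dataset(df, "pD2", "x"), "x"),
                 "intercept-only")
  expect_equal(spec0$terms, character(0))
  expect_equal(spec0$status, "intercept-only")
})

test_that("stepwise entry behaves like a per-term 0.05-level test on pure noise", {
  # per-candidate type-I inclusion rate: family-wise ~1 - 0.95^5, so
  # roughly 0.045 per candidate over five candidates
  n_sel <- withr::with_seed(77, {
    vapply(1:200, function(r) {
      df <- tibble::tibble(compound_id = 1:15)
      for (j in 1:5) df[[paste0("x", j)]] <- rnorm(15)
      df$pKi <- rnorm(15)
      d <- as_qsar_dataset(df, "pKi", paste0("x", 1:5))
      suppressWarnings(length(stepwise_select(d, paste0("x", 1:5))$terms))
    }, numeric(1))
  })
  per_candidate_rate <- sum(n_sel) / (200 * 5)
  expect_gt(per_candidate_rate, 0.01)
  expect_lt(per_candidate_rate, 0.15)
})
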