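# Shared fixtures and independent oracles for the suite.

.tlcqsar_cache <- new.env(parent = emptyenv())

study_tables <- function() {
  if (is.null(.tlcqsar_cache$tables)) {
    .tlcqsar_cache$tables <- load_tables()
  }
  .tlcqsar_cache$tables
}

# Brute-force OLS oracle: solve the normal equations directly, independent
# of the lm-based fitting path.
ols_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  beta <- solve(crossprod(X1), crossprod(X1, y))
  fitted <- drop(X1 %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  list(beta = drop(beta), fitted = fitted, rss = rss, r2 = 1 - rss / tss)
}

# Hat-matrix shortcut for OLS leave-one-out: PRESS = sum((e_i/(1-h_ii))^2).
hat_press_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  H <- X1 %*% solve(crossprod(X1)) %*% t(X1)
  e <- y - H %*% y
  sum((e / (1 - diag(H)))^2)
}

# Wrap a plain tibble as an assembled dataset (for constructed edge cases
# that the fixture loader would not produce).
as_qsar_dataset <- function(df, response, terms, phase = "DS_A") {
  out <- tibble::as_tibble(df)
  attr(out, "response") <- response
  attr(out, "terms") <- terms
  attr(out, "phase") <- phase
  class(out) <- c("qsar_dataset", class(out))
  out
}

# Assembled datasets for the three final study models.
eq6_data <- function() assemble_dataset(study_tables(), "pD2", c("C-S4", "C-S5"), "DS_A")
eq5_data <- function() assemble_dataset(study_tables(), "pKi", c("HD", "C-S5", "logP", "C-S4"), "DS_B")
eq15_data <- function() assemble_dataset(study_tables(), "pA2", c("C-S6", "dHf", "logP"), "DS_B")

# Absolute-tolerance comparison for published-value checks (testthat's
# `tolerance` is relative, which is not what printed-precision slack means).
expect_near <- function(object, expected, tol) {
  act <- testthat::quasi_label(rlang::enquo(object))
  testthat::expect(
    is.finite(act$val) && abs(act$val - expected) <= tol,
    sprintf("%s (= %.6f) differs from %.4f by %.4f, above the allowed %.3f",
            act$lab, act$val, expected, abs(act$val - expected), tol)
  )
  invisible(act$val)
}
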