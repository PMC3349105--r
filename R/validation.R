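new_qsar_cv <- function(kind, predictions, press, q2, n, p, extra = list()) {
  structure(
    c(list(kind = kind, predictions = predictions, PRESS = press, Q2 = q2,
           S_PRESS = sqrt(press / n), SDEP = sqrt(press / n),
           SDEP_df = sqrt(press / (n - p - 1)), n = n, p = p), extra),
    class = "qsar_cv"
  )
}

#' @export
print.qsar_cv <- function(x, ...) {
  cat(sprintf("<qsar_cv %s> n = %d: PRESS = %.4f, Q2 = %.4f, S_PRESS = %.4f\n",
              x$kind, x$n, x$PRESS, x$Q2, x$S_PRESS))
  invisible(x)
}

#' Leave-one-out cross-validation of an activity model
#'
#' For each compound in the dataset, refits the model (the term set stays
#' fixed; coefficients are re-estimated) on the remaining n - 1 compounds
#' and predicts the held-out activity. Reports PRESS (the sum of squared
#' held-out prediction errors), the cross-validated squared correlation
#' Q2 = 1 - PRESS/TSS (TSS about the full-sample mean), S_PRESS =
#' sqrt(PRESS/n), SDEP on the same formula, and a degrees-of-freedom
#' variant `SDEP_df` = sqrt(PRESS/(n - p - 1)).
#'
#' Each fold is an explicit refit; for OLS this agrees with the
#' hat-matrix deleted-residual identity to numerical precision.
#'
#' @param data A `qsar_dataset`.
#' @return A `qsar_cv` with per-compound predictions; see [tidy()] and
#'   [glance()] methods.
#' @export
#' @examples
#' tabs <- load_tables()
#' load_tables() |>
#'   assemble_dataset("pD2", c("C-S4", "C-S5"), "DS_A") |>
#'   loo_crossval()
loo_crossval <- function(data) {
  stopifnot(inherits(data, "qsar_dataset"))
  response <- dataset_response(data)
  terms <- dataset_terms(data)
  n <- nrow(data)
  p <- length(terms)
  if (n < p + 3) {
    abort(sprintf("n = %d leaves too few rows per fold for %d predictor(s)", n, p))
  }
  fm <- dataset_formula(response, terms)
  y <- data[[response]]
  pred <- vapply(seq_len(n), function(i) {
    train <- data[-i, , drop = FALSE]
    if (p > 0 && qr(as.matrix(train[terms]))$rank < p) {
      abort(sprintf("Fold leaving out compound %d is rank deficient", data$compound_id[i]))
    }
    unname(predict(lm(fm, data = train), newdata = data[i, , drop = FALSE]))
  }, numeric(1))
  press <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  new_qsar_cv(
    "LOO",
    tibble::tibble(compound_id = data$compound_id, observed = y,
                   predicted = pred, deleted_residual = y - pred),
    press, 1 - press / tss, n, p
  )
}

#' Leave-N-out cross-validation of an activity model
#'
#' Per repetition, compounds are randomly partitioned (seeded) into groups
#' of size `N` (the last group may be smaller); each group is predicted by
#' a model refit on the remainder, giving one PRESS and Q2 per repetition.
#' The reported Q2 is the mean over repetitions — the usual choice for
#' small compound sets, where a single random partition is too noisy.
#' `N = 1` reduces exactly to [loo_crossval()] whatever the seed.
#'
#' @param data A `qsar_dataset`.
#' @param N Group size; `1 <= N <= n/3` (N = 1 is LOO).
#' @param repetitions Number of random partitions; default 1000.
#' @param seed Integer seed; the partition stream is fully reproducible
#'   and global RNG state is left untouched.
#' @return A `qsar_cv` with per-repetition Q2 values in `$per_repetition`.
#' @export
lno_crossval <- function(data, N = 3, repetitions = 1000, seed = 1) {
  stopifnot(inherits(data, "qsar_dataset"))
  n <- nrow(data)
  p <- length(dataset_terms(data))
  if (N == 1) {
    out <- loo_crossval(data)
    out$kind <- "LNO"
    out$N <- 1L
    out$repetitions <- as.integer(repetitions)
    out$seed <- as.integer(seed)
    out$per_repetition <- tibble::tibble(
      repetition = seq_len(repetitions), PRESS = out$PRESS, Q2 = out$Q2
    )
    return(out)
  }
  if (N < 1 || N > n / 3) {
    abort(sprintf("N = %d infeasible for n = %d (need 1 <= N <= n/3)", N, n))
  }
  response <- dataset_response(data)
  fm <- dataset_formula(response, dataset_terms(data))
  y <- data[[response]]
  tss <- sum((y - mean(y))^2)

  one_rep <- function() {
    ord <- sample.int(n)
    groups <- split(ord, ceiling(seq_along(ord) / N))
    pred <- numeric(n)
    for (g in groups) {
      fit <- lm(fm, data = data[-g, , drop = FALSE])
      pred[g] <- predict(fit, newdata = data[g, , drop = FALSE])
    }
    press <- sum((y - pred)^2)
    c(press, 1 - press / tss)
  }
  reps <- withr::with_seed(seed, vapply(seq_len(repetitions),
                                        function(i) one_rep(), numeric(2)))
  per_rep <- tibble::tibble(repetition = seq_len(repetitions),
                            PRESS = reps[1, ], Q2 = reps[2, ])
  new_qsar_cv(
    "LNO", NULL, mean(per_rep$PRESS), mean(per_rep$Q2), n, p,
    extra = list(N = as.integer(N), repetitions = as.integer(repetitions),
                 seed = as.integer(seed), per_repetition = per_rep)
  )
}

#' @rdname loo_crossval
#' @param x A `qsar_cv`.
#' @param ... Unused.
#' @export
tidy.qsar_cv <- function(x, ...) {
  if (!is.null(x$predictions)) x$predictions else x$per_repetition
}

#' @rdname loo_crossval
#' @export
glance.qsar_cv <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, n = x$n,
    Q2 = x$Q2, PRESS = x$PRESS, S_PRESS = x$S_PRESS,
    SDEP = x$SDEP, SDEP_df = x$SDEP_df,
    N = x$N %||% NA_integer_,
    repetitions = x$repetitions %||% NA_integer_
  )
}

#' Reliability criteria for a validated model
#'
#' Applies the usual acceptance battery for small-set QSAR models:
#' R2 > 0.6 and Q2(LOO) > 0.5; R2 at least as large as both Q2(LOO) and
#' Q2(LNO); the two cross-validated Q2 values within `tol` of each other
#' (the operational reading of "Q2_LOO approximately equal to Q2_LNO");
#' and adjusted R2 below R2 (no overparameterization). The model passes
#' only if every flag holds.
#'
#' @param fit A `qsar_fit`.
#' @param loo,lno Matching `qsar_cv` results for the same model.
#' @param tol Allowed |Q2_LOO - Q2_LNO| gap; default 0.1.
#' @return A `qsar_reliability`: tibble of criterion flags plus the
#'   overall verdict in the `pass` attribute (also a column).
#' @export
reliability_check <- function(fit, loo, lno, tol = 0.1) {
  stopifnot(inherits(fit, "qsar_fit"), inherits(loo, "qsar_cv"),
            inherits(lno, "qsar_cv"))
  if (loo$n != fit$n || lno$n != fit$n || loo$p != fit$p || lno$p != fit$p) {
    abort("Fit and cross-validation results refer to different models")
  }
  flags <- tibble::tibble(
    criterion = c("R2 > 0.6", "Q2_LOO > 0.5", "R2 >= Q2_LOO", "R2 >= Q2_LNO",
                  sprintf("|Q2_LOO - Q2_LNO| <= %g", tol), "R2_adj < R2"),
    value = c(fit$r.squared, loo$Q2, fit$r.squared - loo$Q2,
              fit$r.squared - lno$Q2, abs(loo$Q2 - lno$Q2),
              fit$r.squared - fit$adj.r.squared),
    pass = c(fit$r.squared > 0.6, loo$Q2 > 0.5, fit$r.squared >= loo$Q2,
             fit$r.squared >= lno$Q2, abs(loo$Q2 - lno$Q2) <= tol,
             fit$adj.r.squared < fit$r.squared)
  )
  structure(flags, overall = all(flags$pass),
            class = c("qsar_reliability", class(flags)))
}

#' @export
print.qsar_reliability <- function(x, ...) {
  cat(sprintf("<qsar_reliability> overall: %s\n",
              if (attr(x, "overall")) "PASS" else "FAIL"))
  NextMethod()
  invisible(x)
}

#' Observed, predicted and residual activities for a fitted model
#'
#' Evaluates the fitted equation for every compound of a dataset and
#' tabulates observed activity, prediction and residual (observed minus
#' predicted) — the standard observed/predicted comparison table.
#'
#' @param fit A `qsar_fit`.
#' @param data Dataset to predict; defaults to the fitting data. Must
#'   contain the model's terms.
#' @param digits Optional rounding for a display-ready table; `NULL`
#'   (default) keeps full precision.
#' @return A tibble with `compound_id`, `observed`, `predicted`,
#'   `residual`.
#' @export
prediction_table <- function(fit, data = fit$data, digits = NULL) {
  stopifnot(inherits(fit, "qsar_fit"))
  missing_terms <- setdiff(fit$spec$terms, names(data))
  if (length(missing_terms)) {
    abort(sprintf("Dataset lacks model term(s): %s",
                  paste(missing_terms, collapse = ", ")))
  }
  pred <- unname(predict(fit$lm, newdata = data))
  obs <- data[[fit$spec$response]]
  out <- tibble::tibble(
    compound_id = data$compound_id,
    observed = obs,
    predicted = pred,
    residual = obs - pred
  )
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(c("observed", "predicted", "residual"),
                                            ~ round(.x, digits)))
  }
  out
}
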