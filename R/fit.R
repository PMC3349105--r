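backtick <- function(x) sprintf("`%s`", x)

dataset_formula <- function(response, terms) {
  rhs <- if (length(terms)) paste(backtick(terms), collapse = " + ") else "1"
  stats::as.formula(paste(backtick(response), "~", rhs))
}

#' Describe one activity model
#'
#' A model specification names the response activity, the ordered
#' predictor terms and the mobile phase supplying the chromatographic
#' features — everything needed to assemble data and fit.
#'
#' @param response One of `"pKi"`, `"pD2"`, `"pA2"`.
#' @param terms Character vector of predictor names.
#' @param phase Mobile phase, `"DS_A"` or `"DS_B"`.
#' @param label Optional short label (e.g. `"eq6"`).
#' @param status `"ok"`, or `"intercept-only"` when selection found no
#'   admissible term.
#' @return An object of class `qsar_spec`.
#' @export
model_spec <- function(response, terms, phase = c("DS_A", "DS_B"),
                       label = NULL, status = "ok") {
  phase <- match.arg(phase)
  response <- match.arg(response, ACTIVITIES)
  terms <- as.character(terms)
  if (anyDuplicated(terms)) abort("Duplicate terms in model spec")
  structure(
    list(response = response, terms = terms, phase = phase,
         label = label %||% paste0(response, "~", paste(terms, collapse = "+")),
         status = status),
    class = "qsar_spec"
  )
}

#' @export
print.qsar_spec <- function(x, ...) {
  cat(sprintf("<qsar_spec %s> %s ~ %s  [phase %s%s]\n", x$label, x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$phase,
              if (identical(x$status, "ok")) "" else paste0("; ", x$status)))
  invisible(x)
}

#' Fit an ordinary-least-squares activity model
#'
#' Fits the response of an assembled dataset on its term columns with an
#' intercept, and computes the fit-statistics suite used throughout the
#' package: the multiple correlation coefficient R (reported as
#' +sqrt(R2)), R2, adjusted R2, the variance ratio F with its p-value,
#' and the standard error of estimate s = sqrt(RSS / (n - p - 1)).
#'
#' @param data A `qsar_dataset` from [assemble_dataset()].
#' @param label Optional label carried into reports.
#' @return An object of class `qsar_fit`. Use [tidy()] for the
#'   coefficient table, [glance()] for the one-row statistics summary,
#'   [augment()] / [prediction_table()] for per-compound predictions and
#'   [autoplot()] for an observed-versus-predicted plot.
#' @export
#' @examples
#' tabs <- load_tables()
#' fit <- load_tables() |>
#'   assemble_dataset("pD2", c("C-S4", "C-S5"), phase = "DS_A") |>
#'   fit_qsar()
#' glance(fit)
fit_qsar <- function(data, label = NULL) {
  stopifnot(inherits(data, "qsar_dataset"))
  response <- dataset_response(data)
  terms <- dataset_terms(data)
  n <- nrow(data)
  p <- length(terms)
  if (n < p + 2) {
    abort(sprintf("n = %d is too small to fit %d predictor(s) plus intercept", n, p))
  }
  if (p > 0 && qr(as.matrix(data[terms]))$rank < p) {
    abort("Predictor matrix is rank deficient")
  }

  fm <- dataset_formula(response, terms)
  lmfit <- lm(fm, data = data)
  # summary() warns on numerically perfect fits; noiseless synthetic
  # datasets are a legitimate input here
  sm <- suppressWarnings(summary(lmfit))

  y <- data[[response]]
  rss <- sum(stats::residuals(lmfit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  fstat <- if (p > 0) (r2 / p) / ((1 - r2) / (n - p - 1)) else NA_real_
  p_value <- if (p > 0) pf(fstat, p, n - p - 1, lower.tail = FALSE) else NA_real_

  coefs <- tibble::tibble(
    term = c("(Intercept)", terms),
    estimate = unname(coef(lmfit)),
    std.error = unname(sm$coefficients[, "Std. Error"]),
    statistic = unname(sm$coefficients[, "t value"]),
    p.value = unname(sm$coefficients[, "Pr(>|t|)"])
  )

  structure(
    list(
      spec = model_spec(response, terms, dataset_phase(data),
                        label = label),
      lm = lmfit,
      coefficients = coefs,
      n = n, p = p,
      r = sqrt(max(r2, 0)),
      r.squared = r2,
      adj.r.squared = r2_adj,
      statistic = fstat,
      sigma = sqrt(rss / (n - p - 1)),
      p.value = p_value,
      rss = rss, tss = tss,
      data = data
    ),
    class = "qsar_fit"
  )
}

#' @export
print.qsar_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<qsar_fit %s> %s ~ %s  [phase %s]\n", x$spec$label,
              x$spec$response,
              if (x$p) paste(x$spec$terms, collapse = " + ") else "1",
              x$spec$phase))
  cat(sprintf("  n = %d, R = %.2f, R2 = %.2f, R2adj = %.2f, F = %.4f, s = %.4f, p = %.4f\n",
              x$n, x$r, x$r.squared, x$adj.r.squared, x$statistic, x$sigma,
              x$p.value))
  print(dplyr::mutate(x$coefficients,
                      dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits))))
  invisible(x)
}

#' @rdname fit_qsar
#' @param x A `qsar_fit`.
#' @param ... Unused.
#' @export
tidy.qsar_fit <- function(x, ...) x$coefficients

#' @rdname fit_qsar
#' @export
glance.qsar_fit <- function(x, ...) {
  tibble::tibble(
    label = x$spec$label,
    response = x$spec$response,
    phase = x$spec$phase,
    n = x$n, p = x$p,
    r = x$r,
    r.squared = x$r.squared,
    adj.r.squared = x$adj.r.squared,
    statistic = x$statistic,
    sigma = x$sigma,
    p.value = x$p.value
  )
}

#' @rdname fit_qsar
#' @export
augment.qsar_fit <- function(x, ...) {
  prediction_table(x)
}

#' Pearson correlation matrix of a modelling dataset
#'
#' Pairwise Pearson correlations over the rows of an assembled dataset,
#' i.e. over the compounds with a non-missing response — the subset a fit
#' on that dataset would use. Used to inspect descriptor intercorrelation
#' before model building.
#'
#' @param data A `qsar_dataset`.
#' @param include_response Include the response column? Default `TRUE`.
#' @return A `qsar_cormat`: the correlation matrix with attributes `n`
#'   (rows used) and `variables`. [tidy()] gives the long pair form,
#'   [autoplot()] a tile plot.
#' @export
#' @examples
#' tabs <- load_tables()
#' cm <- correlation_matrix(assemble_dataset(tabs, "pD2", c("C-S4", "C-S5"), "DS_A"))
#' round(unclass(cm), 2)
correlation_matrix <- function(data, include_response = TRUE) {
  stopifnot(inherits(data, "qsar_dataset"))
  vars <- dataset_terms(data)
  if (include_response) vars <- c(vars, dataset_response(data))
  if (nrow(data) < 3) abort("Need at least 3 rows for a correlation matrix")
  m <- as.matrix(data[vars])
  degenerate <- vars[apply(m, 2, sd) == 0]
  if (length(degenerate)) {
    abort(sprintf("Zero-variance column(s): %s", paste(degenerate, collapse = ", ")))
  }
  cm <- cor(m, method = "pearson")
  structure(cm, n = nrow(data), variables = vars, class = c("qsar_cormat", "matrix"))
}

#' @export
print.qsar_cormat <- function(x, digits = 2, ...) {
  cat(sprintf("<qsar_cormat> Pearson r over n = %d compounds\n", attr(x, "n")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' @rdname correlation_matrix
#' @param x A `qsar_cormat`.
#' @param ... Unused.
#' @export
tidy.qsar_cormat <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(m, rownames = "var1") |>
    tidyr::pivot_longer(-"var1", names_to = "var2", values_to = "r")
}

#' Prune candidate predictors by pairwise collinearity
#'
#' Applies the pairwise rule used before model building: while any two
#' candidates correlate with |r| above `threshold` (over the compounds of
#' the dataset), one of them is removed. The most-correlated offending
#' pair is resolved first, dropping the member with the smaller |r|
#' against the response; exact ties are broken in favour of the earlier
#' candidate in `candidates`. The result is deterministic and every
#' surviving pair satisfies |r| <= `threshold`.
#'
#' @param data A `qsar_dataset` whose columns include all `candidates`.
#' @param candidates Character vector of candidate predictor names.
#' @param threshold Pairwise |r| limit; default 0.5.
#' @return Character vector: the retained candidates, in input order.
#' @export
collinearity_filter <- function(data, candidates, threshold = 0.5) {
  stopifnot(inherits(data, "qsar_dataset"))
  candidates <- as.character(candidates)
  unknown <- setdiff(candidates, names(data))
  if (length(unknown)) {
    abort(sprintf("Candidate(s) not in dataset: %s", paste(unknown, collapse = ", ")))
  }
  y <- data[[dataset_response(data)]]
  keep <- candidates
  while (length(keep) > 1) {
    cm <- abs(cor(as.matrix(data[keep]), method = "pearson"))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- keep[idx[1]]; b <- keep[idx[2]]
    ry <- abs(c(cor(data[[a]], y), cor(data[[b]], y)))
    # drop the member less correlated with the response; ties keep the
    # earlier candidate in the original list
    drop <- if (ry[1] < ry[2]) a
            else if (ry[2] < ry[1]) b
            else keep[max(match(c(a, b), candidates))]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Forward-stepwise term selection with backward checks
#'
#' At each step the candidate with the smallest partial-F p-value below
#' `alpha_enter` joins the model; after every addition, any term whose
#' p-value has risen above `alpha_remove` is dropped (and returns to the
#' candidate pool). Selection stops when no candidate qualifies or when
#' `max_terms` is reached. With a small compound set the default cap
#' `floor(n/5) + 1`, at most 4, guards against overfitting.
#'
#' @param data A `qsar_dataset` whose columns include all `candidates`.
#' @param candidates Candidate predictor names, normally pre-filtered with
#'   [collinearity_filter()].
#' @param alpha_enter Entry significance level; default 0.05.
#' @param alpha_remove Removal significance level; default 0.10.
#' @param max_terms Cap on selected terms; default `floor(n/5) + 1`,
#'   capped at 4.
#' @return A `qsar_spec`. If nothing qualifies, an intercept-only spec
#'   with `status = "intercept-only"` and a warning.
#' @export
stepwise_select <- function(data, candidates, alpha_enter = 0.05,
                            alpha_remove = 0.10, max_terms = NULL) {
  stopifnot(inherits(data, "qsar_dataset"))
  candidates <- as.character(candidates)
  unknown <- setdiff(candidates, names(data))
  if (length(unknown)) {
    abort(sprintf("Candidate(s) not in dataset: %s", paste(unknown, collapse = ", ")))
  }
  n <- nrow(data)
  max_terms <- max_terms %||% min(floor(n / 5) + 1, 4)
  response <- dataset_response(data)

  term_pvals <- function(terms) {
    fm <- dataset_formula(response, terms)
    # perfect interpolation mid-selection is legitimate; silence summary()
    sm <- suppressWarnings(summary(lm(fm, data = data)))$coefficients
    setNames(sm[-1, "Pr(>|t|)"], terms)
  }

  selected <- character()
  pool <- candidates
  repeat {
    if (length(selected) >= max_terms || !length(pool)) break
    entry_p <- vapply(pool, function(cand) {
      # partial-F p-value of the candidate given the current terms; for a
      # single added coefficient this equals the squared-t test p-value
      unname(term_pvals(c(selected, cand))[cand])
    }, numeric(1))
    if (min(entry_p) >= alpha_enter) break
    best <- pool[which.min(entry_p)]
    selected <- c(selected, best)
    pool <- setdiff(pool, best)
    repeat {
      pv <- term_pvals(selected)
      if (!length(pv) || max(pv) <= alpha_remove) break
      worst <- names(pv)[which.max(pv)]
      selected <- setdiff(selected, worst)
      pool <- union(pool, worst)
      if (!length(selected)) break
    }
  }

  if (!length(selected)) {
    warn(sprintf("No candidate met alpha_enter = %g for %s; returning intercept-only spec",
                 alpha_enter, response))
    return(model_spec(response, character(), dataset_phase(data),
                      status = "intercept-only"))
  }
  model_spec(response, selected, dataset_phase(data))
}
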