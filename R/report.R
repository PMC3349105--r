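#' Registry of the study's fifteen regression-model structures
#'
#' The model structures fitted in the study: for each activity, models
#' built from chromatographic features of one mobile phase, from
#' molecular descriptors alone, or from both. Descriptor-only models
#' (eq3, eq8, eq13) use no chromatographic column; their `phase` is kept
#' at `"DS_A"` for uniformity and has no effect.
#'
#' @return A tibble with columns `label`, `response`, `terms`
#'   (list-column), `phase`.
#' @export
equation_registry <- function() {
  tibble::tribble(
    ~label, ~response, ~terms, ~phase,
    "eq1",  "pKi", c("C-S2", "S1/C", "S3/C", "S2/C"),   "DS_A",
    "eq2",  "pKi", c("C-S5", "S5/C", "C-S4", "C-S1"),   "DS_B",
    "eq3",  "pKi", c("Q_N", "mu", "logD"),              "DS_A",
    "eq4",  "pKi", c("HD", "logP", "C-S5", "V_m"),      "DS_A",
    "eq5",  "pKi", c("HD", "C-S5", "logP", "C-S4"),     "DS_B",
    "eq6",  "pD2", c("C-S4", "C-S5"),                   "DS_A",
    "eq7",  "pD2", c("S5/C", "C-S4"),                   "DS_B",
    "eq8",  "pD2", c("logD", "eps_LUMO"),               "DS_A",
    "eq9",  "pD2", c("C-S4", "C-S5", "Q_N"),            "DS_A",
    "eq10", "pD2", c("logD", "C-S4"),                   "DS_B",
    "eq11", "pA2", c("C-S7", "S1", "S4/C"),             "DS_A",
    "eq12", "pA2", c("C-S6", "C-S3", "S1/C"),           "DS_B",
    "eq13", "pA2", c("dHf", "mu", "R_m"),               "DS_A",
    "eq14", "pA2", c("mu", "S3/C", "C-S7"),             "DS_A",
    "eq15", "pA2", c("C-S6", "dHf", "logP"),            "DS_B"
  )
}

# Published statistics the reproduction run compares itself against.
printed_reference <- function() {
  fit_stats <- tibble::tribble(
    ~label, ~R, ~R2, ~F, ~s, ~p, ~n,
    "eq1",  0.83, 0.68,  7.4815, 0.6687, 0.0019, 19,
    "eq2",  0.73, 0.53,  4.0085, 0.8087, 0.0226, 19,
    "eq3",  0.83, 0.69, 11.0470, 0.6387, 0.0004, 19,
    "eq4",  0.78, 0.60,  5.3183, 0.7462, 0.0081, 19,
    "eq5",  0.90, 0.80, 14.6095, 0.5272, 0.0001, 19,
    "eq6",  0.92, 0.84, 26.6280, 0.3654, 0.0001, 13,
    "eq7",  0.68, 0.46,  4.2261, 0.6766, 0.0467, 13,
    "eq8",  0.77, 0.57,  6.7003, 0.6008, 0.0142, 13,
    "eq9",  0.93, 0.86, 19.2116, 0.3560, 0.0003, 13,
    "eq10", 0.77, 0.60,  7.4952, 0.5814, 0.0103, 13,
    "eq11", 0.61, 0.37,  2.3231, 1.0017, 0.1267, 16,
    "eq12", 0.83, 0.69,  8.8524, 0.7026, 0.0022, 16,
    "eq13", 0.83, 0.69,  8.8893, 0.7073, 0.0022, 16,
    "eq14", 0.83, 0.68,  8.6594, 0.7080, 0.0025, 16,
    "eq15", 0.88, 0.78, 14.0194, 0.5934, 0.0003, 16
  )
  validation_stats <- tibble::tribble(
    ~label, ~R2_adj, ~Q2_LOO, ~SDEP, ~PRESS, ~S_PRESS, ~Q2_LNO,
    "eq5",  0.75, 0.70, 0.5883, 6.3052, 0.5761, 0.63,
    "eq6",  0.81, 0.73, 0.4522, 2.3390, 0.4242, 0.70,
    "eq15", 0.72, 0.57, 0.7633, 8.6092, 0.7335, 0.55
  )
  list(fit = fit_stats, validation = validation_stats)
}

write_report_tsv <- function(df, path, digits = NULL) {
  if (!is.null(digits)) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric) & !dplyr::any_of(c("compound_id", "n", "p")),
                                          ~ round(.x, digits)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "—")
  path
}

write_run_metadata <- function(out_dir, what, params) {
  path <- file.path(out_dir, sprintf("%s_run.txt", what))
  lines <- c(
    sprintf("# run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("%s = %s", names(params), vapply(params, function(x)
      paste(format(x), collapse = ","), ""))
  )
  writeLines(lines, path)
  path
}

#' Fit, validate and report one activity model
#'
#' Runs the full single-model pipeline: assemble the dataset, fit OLS,
#' leave-one-out and leave-N-out cross-validation, reliability check;
#' then writes a statistics report (coefficients with standard errors; R,
#' R2, adjusted R2, F, s, p; Q2_LOO, SDEP, PRESS, S_PRESS, Q2_LNO, n), an
#' observed/predicted/residual table and a run-metadata file into
#' `out_dir`.
#'
#' @param tables A `qsar_tables` object.
#' @param response,terms,phase Model definition as in
#'   [assemble_dataset()].
#' @param label Report file prefix and model label.
#' @param out_dir Output directory; created if absent.
#' @param lno_N,lno_repetitions,seed Leave-N-out settings (see
#'   [lno_crossval()]).
#' @param tol Q2 agreement tolerance for [reliability_check()].
#' @return Invisibly, a list with `fit`, `loo`, `lno`, `reliability` and
#'   the written `files`.
#' @export
fit_report <- function(tables, response, terms, phase, label = "model",
                       out_dir = ".", lno_N = 3, lno_repetitions = 1000,
                       seed = 1, tol = 0.1) {
  data <- assemble_dataset(tables, response, terms, phase)
  fit <- fit_qsar(data, label = label)
  loo <- loo_crossval(data)
  lno <- lno_crossval(data, N = lno_N, repetitions = lno_repetitions, seed = seed)
  rel <- reliability_check(fit, loo, lno, tol = tol)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stats_row <- dplyr::bind_cols(
    glance(fit),
    tibble::tibble(Q2_LOO = loo$Q2, SDEP = loo$SDEP, PRESS = loo$PRESS,
                   S_PRESS = loo$S_PRESS, Q2_LNO = lno$Q2,
                   reliability = if (attr(rel, "overall")) "pass" else "fail")
  )
  files <- c(
    statistics = write_report_tsv(stats_row, file.path(out_dir, paste0(label, "_statistics.tsv"))),
    coefficients = write_report_tsv(tidy(fit), file.path(out_dir, paste0(label, "_coefficients.tsv"))),
    reliability = write_report_tsv(tibble::as_tibble(rel), file.path(out_dir, paste0(label, "_reliability.tsv"))),
    predictions = write_report_tsv(prediction_table(fit), file.path(out_dir, paste0(label, "_predictions.tsv"))),
    metadata = write_run_metadata(out_dir, label,
                                  list(response = response, terms = terms,
                                       phase = phase, lno_N = lno_N,
                                       lno_repetitions = lno_repetitions,
                                       seed = seed, tol = tol))
  )
  invisible(list(fit = fit, loo = loo, lno = lno, reliability = rel,
                 files = files))
}

#' Reproduce the study's result tables end to end
#'
#' Loads the fixture tables, refits all fifteen registered model
#' structures, cross-validates the three final models (eq5, eq6, eq15),
#' recomputes the two correlation matrices and the observed/predicted
#' activity tables, and writes one file per result table plus a
#' comparison file listing the published statistics against the
#' recomputed ones with absolute differences. Full-precision values are
#' written alongside every rounded view.
#'
#' @param fixture_dir Directory with the study tables; defaults to the
#'   packaged ones.
#' @param out_dir Output directory; created if absent.
#' @param seed,lno_N,lno_repetitions Leave-N-out settings for the
#'   validated models.
#' @return Invisibly, a named list of written file paths.
#' @export
reproduce_study <- function(fixture_dir = qsar_fixture_dir(), out_dir = ".",
                            seed = 1, lno_N = 3, lno_repetitions = 1000) {
  tables <- load_tables(fixture_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reg <- equation_registry()
  ref <- printed_reference()

  fits <- purrr::pmap(reg, function(label, response, terms, phase) {
    fit_qsar(assemble_dataset(tables, response, terms, phase), label = label)
  })
  names(fits) <- reg$label

  fit_summary <- purrr::map_dfr(fits, glance)
  files <- list()
  files$fit_statistics <- write_report_tsv(
    fit_summary, file.path(out_dir, "fit_statistics.tsv"))

  validated <- c("eq5", "eq6", "eq15")
  val_rows <- purrr::map_dfr(validated, function(lab) {
    data <- fits[[lab]]$data
    loo <- loo_crossval(data)
    lno <- lno_crossval(data, N = lno_N, repetitions = lno_repetitions, seed = seed)
    dplyr::bind_cols(
      glance(fits[[lab]]),
      tibble::tibble(Q2_LOO = loo$Q2, SDEP = loo$SDEP, SDEP_df = loo$SDEP_df,
                     PRESS = loo$PRESS, S_PRESS = loo$S_PRESS, Q2_LNO = lno$Q2)
    )
  })
  files$validation_statistics <- write_report_tsv(
    val_rows, file.path(out_dir, "validation_statistics.tsv"))

  coef_rows <- purrr::map_dfr(validated, function(lab)
    dplyr::mutate(tidy(fits[[lab]]), label = lab, .before = 1))
  files$final_coefficients <- write_report_tsv(
    coef_rows, file.path(out_dir, "final_coefficients.tsv"))

  # correlation matrix over the agonist-potency subset (the 13 compounds
  # with pD2): the unambiguous matrix of the published pair
  cmB <- correlation_matrix(fits[["eq6"]]$data)
  files$correlation_pD2 <- write_report_tsv(
    tidy(cmB), file.path(out_dir, "correlation_pD2_subset.tsv"), digits = 4)

  # variable pool of the two final DS_B models against pKi and pA2; the
  # published compound subset is ambiguous here, so pairwise-complete
  # compounds are used and the subset sizes are recorded in the metadata
  featB <- derive_features(tables$retention$DS_B)
  poolA <- dplyr::left_join(featB[c("compound_id", "C-S4", "C-S5", "C-S6")],
                            tables$descriptors[c("compound_id", "dHf", "logP", "HD")],
                            by = "compound_id")
  poolA <- dplyr::left_join(poolA, tables$activities[c("compound_id", "pA2", "pKi")],
                            by = "compound_id")
  cmA <- cor(as.matrix(poolA[-1]), use = "pairwise.complete.obs")
  files$correlation_pool <- write_report_tsv(
    tibble::as_tibble(cmA, rownames = "variable"),
    file.path(out_dir, "correlation_variable_pool.tsv"), digits = 4)

  preds <- purrr::map(validated, function(lab) {
    prediction_table(fits[[lab]]) |>
      dplyr::rename_with(~ paste0(fits[[lab]]$spec$response, "_", .x, "_", lab),
                         -"compound_id")
  })
  pred_wide <- purrr::reduce(preds, dplyr::full_join, by = "compound_id") |>
    dplyr::arrange(.data$compound_id)
  files$predictions <- write_report_tsv(
    pred_wide, file.path(out_dir, "observed_predicted.tsv"), digits = 2)
  files$predictions_full <- write_report_tsv(
    pred_wide, file.path(out_dir, "observed_predicted_full.tsv"))

  comparison <- dplyr::bind_rows(
    tidyr::pivot_longer(ref$fit, -"label", names_to = "statistic",
                        values_to = "printed") |>
      dplyr::left_join(
        fit_summary |>
          dplyr::transmute(.data$label, R = .data$r, R2 = .data$r.squared,
                           `F` = .data$statistic, s = .data$sigma,
                           p = .data$p.value, n = as.numeric(.data$n)) |>
          tidyr::pivot_longer(-"label", names_to = "statistic",
                              values_to = "recomputed"),
        by = c("label", "statistic")
      ),
    tidyr::pivot_longer(ref$validation, -"label", names_to = "statistic",
                        values_to = "printed") |>
      dplyr::left_join(
        val_rows |>
          dplyr::transmute(.data$label, R2_adj = .data$adj.r.squared,
                           Q2_LOO = .data$Q2_LOO, SDEP = .data$SDEP,
                           PRESS = .data$PRESS, S_PRESS = .data$S_PRESS,
                           Q2_LNO = .data$Q2_LNO) |>
          tidyr::pivot_longer(-"label", names_to = "statistic",
                              values_to = "recomputed"),
        by = c("label", "statistic")
      )
  ) |>
    dplyr::mutate(abs_difference = abs(.data$printed - .data$recomputed))
  files$comparison <- write_report_tsv(
    comparison, file.path(out_dir, "comparison_printed_vs_recomputed.tsv"))

  files$metadata <- write_run_metadata(
    out_dir, "reproduction",
    list(fixture_dir = fixture_dir, seed = seed, lno_N = lno_N,
         lno_repetitions = lno_repetitions,
         correlation_pool_note = "pairwise-complete compounds"))
  invisible(files)
}
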