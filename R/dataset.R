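#' Path to the packaged study tables
#'
#' The package ships the complete study data as plain-text, tab-separated
#' fixtures: known biological activities (`activities.tsv`), RM retention
#' values for the two developing-solvent systems (`retention_dsa.tsv`,
#' `retention_dsb.tsv`) and the 19 calculated molecular descriptors
#' (`descriptors.tsv`).
#'
#' @return Directory containing the fixture files.
#' @export
#' @examples
#' list.files(qsar_fixture_dir())
qsar_fixture_dir <- function() {
  system.file("extdata", package = "tlcqsar", mustWork = TRUE)
}

# Source tables use the typographic minus (U+2212); normalize to ASCII so
# numeric parsing is uniform regardless of how a fixture was transcribed.
normalize_minus <- function(x) {
  gsub("−", "-", x, fixed = TRUE)
}

# Em/en dash and friends mark a missing activity in the source tables.
MISSING_TOKENS <- c("—", "–", "-", "NA", "")

parse_activity_number <- function(x, column, file) {
  x <- trimws(normalize_minus(x))
  out <- rep(NA_real_, length(x))
  keep <- !(x %in% MISSING_TOKENS)
  vals <- suppressWarnings(as.numeric(x[keep]))
  if (anyNA(vals)) {
    abort(sprintf(
      "Malformed value(s) in column '%s' of %s: %s",
      column, file, paste(unique(x[keep][is.na(vals)]), collapse = ", ")
    ))
  }
  out[keep] <- vals
  out
}

parse_strict_number <- function(x, column, file) {
  x <- trimws(normalize_minus(x))
  vals <- suppressWarnings(as.numeric(x))
  if (anyNA(vals)) {
    abort(sprintf(
      "Malformed or missing value(s) in column '%s' of %s: %s",
      column, file, paste(unique(x[is.na(vals)]), collapse = ", ")
    ))
  }
  vals
}

read_delim_raw <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Fixture file not found: %s", path))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  tibble::as_tibble(df)
}

check_compound_ids <- function(ids, file) {
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicated compound_id in %s: %s", file,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(ids != as.integer(ids)) || any(ids < 1)) {
    abort(sprintf("compound_id must be a positive integer in %s", file))
  }
  as.integer(ids)
}

#' Read an activity table
#'
#' Activities are negative-log potency measures: `pKi` (5-HT receptor
#' binding affinity), `pD2` (agonist potency) and `pA2` (antagonist
#' potency). Not every compound has every activity; a dash in the file is
#' read as missing.
#'
#' @param path Path to a tab-separated file with columns `compound_id`,
#'   `name`, `pKi`, `pD2`, `pA2`.
#' @return A tibble with one row per compound.
#' @export
read_activity_table <- function(path) {
  raw <- read_delim_raw(path)
  needed <- c("compound_id", "name", ACTIVITIES)
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort(sprintf("%s lacks column(s): %s", path, paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    compound_id = check_compound_ids(parse_strict_number(raw$compound_id, "compound_id", path), path),
    name = trimws(raw$name)
  )
  for (a in ACTIVITIES) out[[a]] <- parse_activity_number(raw[[a]], a, path)
  out
}

#' Read an RM retention table for one mobile phase
#'
#' Each row holds the RM retention parameter of one compound in the
#' unimpregnated control environment (`C`) and the seven impregnated
#' biochromatographic model environments (`S1`..`S7`). RM values are
#' dimensionless and, for these systems, expected within about
#' \eqn{|RM| \le 2}; values outside that range are flagged with a warning.
#'
#' @param path Path to a tab-separated file with columns `compound_id`,
#'   `C`, `S1`..`S7`.
#' @param phase Mobile-phase label, `"DS_A"` or `"DS_B"`; stored as an
#'   attribute on the returned tibble.
#' @return A tibble with one row per compound; attribute `phase`.
#' @export
read_retention_table <- function(path, phase = c("DS_A", "DS_B")) {
  phase <- match.arg(phase)
  raw <- read_delim_raw(path)
  needed <- c("compound_id", ENVIRONMENTS)
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort(sprintf("%s lacks column(s): %s", path, paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    compound_id = check_compound_ids(parse_strict_number(raw$compound_id, "compound_id", path), path)
  )
  for (e in ENVIRONMENTS) {
    v <- parse_strict_number(raw[[e]], e, path)
    if (any(!is.finite(v))) {
      abort(sprintf("Non-finite RM value in column '%s' of %s", e, path))
    }
    if (any(abs(v) > 2)) {
      warn(sprintf("RM values with |RM| > 2 in column '%s' of %s; check transcription", e, path))
    }
    out[[e]] <- v
  }
  attr(out, "phase") <- phase
  out
}

#' Read a molecular-descriptor table
#'
#' The 19 calculated descriptors per compound (total/binding energy, heat
#' of formation, dipole moment, frontier-orbital energies, surface area,
#' molar volume, hydration energy, logP, molar refractivity,
#' polarizability, molecular weight, nitrogen net charge, logD, pKa, polar
#' surface area and hydrogen-bond donor/acceptor counts). The table must
#' be complete; `HD` and `HA` must be non-negative integers.
#'
#' @param path Path to a tab-separated file with columns `compound_id`
#'   plus the 19 descriptors.
#' @return A tibble with one row per compound.
#' @export
read_descriptor_table <- function(path) {
  raw <- read_delim_raw(path)
  needed <- c("compound_id", DESCRIPTORS)
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort(sprintf("%s lacks column(s): %s", path, paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    compound_id = check_compound_ids(parse_strict_number(raw$compound_id, "compound_id", path), path)
  )
  for (d in DESCRIPTORS) out[[d]] <- parse_strict_number(raw[[d]], d, path)
  for (cnt in c("HD", "HA")) {
    v <- out[[cnt]]
    if (any(v < 0) || any(v != as.integer(v))) {
      abort(sprintf("Column '%s' of %s must hold non-negative integers", cnt, path))
    }
    out[[cnt]] <- as.integer(out[[cnt]])
  }
  out
}

#' Load the full set of study tables from a fixture directory
#'
#' Reads and cross-validates the activity, retention (both mobile phases)
#' and descriptor tables. All tables must cover exactly the same set of
#' compounds; any inconsistency is an error.
#'
#' @param fixture_dir Directory holding `activities.tsv`,
#'   `retention_dsa.tsv`, `retention_dsb.tsv` and `descriptors.tsv`.
#'   Defaults to the packaged study tables.
#' @return An object of class `qsar_tables`: a list with elements
#'   `compounds`, `activities`, `retention` (a list with `DS_A` and
#'   `DS_B`) and `descriptors`.
#' @export
#' @examples
#' tabs <- load_tables()
#' sum(!is.na(tabs$activities$pD2))
load_tables <- function(fixture_dir = qsar_fixture_dir()) {
  activities <- read_activity_table(file.path(fixture_dir, "activities.tsv"))
  retention <- list(
    DS_A = read_retention_table(file.path(fixture_dir, "retention_dsa.tsv"), "DS_A"),
    DS_B = read_retention_table(file.path(fixture_dir, "retention_dsb.tsv"), "DS_B")
  )
  descriptors <- read_descriptor_table(file.path(fixture_dir, "descriptors.tsv"))

  ids <- activities$compound_id
  for (tab in c(retention, list(descriptors))) {
    if (!identical(sort(tab$compound_id), sort(ids))) {
      abort("Tables do not cover the same set of compound ids")
    }
  }

  structure(
    list(
      compounds = dplyr::select(activities, "compound_id", "name"),
      activities = dplyr::select(activities, -"name"),
      retention = retention,
      descriptors = descriptors
    ),
    class = "qsar_tables"
  )
}

#' @export
print.qsar_tables <- function(x, ...) {
  cat(sprintf(
    "<qsar_tables> %d compounds; activities: %s; retention phases: %s; %d descriptors\n",
    nrow(x$activities),
    paste(sprintf("%s (n=%d)", ACTIVITIES,
                  colSums(!is.na(x$activities[ACTIVITIES]))), collapse = ", "),
    paste(names(x$retention), collapse = ", "),
    length(DESCRIPTORS)
  ))
  invisible(x)
}

#' Write a set of study tables to a directory
#'
#' Emits the same tab-separated fixture formats that [load_tables()]
#' reads, so loaded or simulated tables round-trip exactly. Missing
#' activities are written as an em dash.
#'
#' @param tables A `qsar_tables` object.
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "qsar_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) {
    ifelse(is.na(x), "—", trimws(formatC(x, format = "fg", digits = 15)))
  }
  act <- dplyr::left_join(tables$compounds, tables$activities, by = "compound_id")
  act_out <- data.frame(
    compound_id = act$compound_id, name = act$name,
    pKi = fmt(act$pKi), pD2 = fmt(act$pD2), pA2 = fmt(act$pA2),
    check.names = FALSE
  )
  write_tsv_utf8 <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  write_tsv_utf8(act_out, file.path(dir, "activities.tsv"))
  write_tsv_utf8(as.data.frame(tables$retention$DS_A), file.path(dir, "retention_dsa.tsv"))
  write_tsv_utf8(as.data.frame(tables$retention$DS_B), file.path(dir, "retention_dsb.tsv"))
  write_tsv_utf8(as.data.frame(tables$descriptors), file.path(dir, "descriptors.tsv"))
  invisible(dir)
}

#' Assemble an analysis-ready modelling dataset
#'
#' Joins one activity (the response) with any mix of molecular descriptors
#' and derived chromatographic features (raw `C`, `S1`..`S7`, differences
#' `C-S1`..`C-S7`, ratios `S1/C`..`S7/C`) for the requested mobile phase,
#' keeping only compounds with a non-missing response. Column order
#' follows `terms`.
#'
#' @param tables A `qsar_tables` object from [load_tables()] or
#'   [simulate_tables()].
#' @param response One of `"pKi"`, `"pD2"`, `"pA2"`.
#' @param terms Character vector of predictor names, possibly empty (an
#'   intercept-only dataset).
#' @param phase Mobile phase supplying the chromatographic features.
#' @return A tibble of class `qsar_dataset` with columns `compound_id`,
#'   the response, then the terms; attributes `response`, `terms`,
#'   `phase`.
#' @export
#' @examples
#' tabs <- load_tables()
#' d <- assemble_dataset(tabs, "pD2", c("C-S4", "C-S5"), phase = "DS_A")
#' dim(d)
assemble_dataset <- function(tables, response, terms = character(),
                             phase = c("DS_A", "DS_B")) {
  stopifnot(inherits(tables, "qsar_tables"))
  phase <- match.arg(phase)
  response <- match.arg(response, ACTIVITIES)
  terms <- as.character(terms)
  if (anyDuplicated(terms)) {
    abort("Duplicate predictor names in `terms`")
  }

  feats <- derive_features(tables$retention[[phase]])
  registry <- c(setdiff(names(feats), "compound_id"),
                setdiff(names(tables$descriptors), "compound_id"))
  unknown <- setdiff(terms, registry)
  if (length(unknown)) {
    abort(sprintf("Unknown term(s): %s. Available: descriptors and derived features of phase %s.",
                  paste(unknown, collapse = ", "), phase))
  }

  full <- dplyr::left_join(tables$activities, feats, by = "compound_id")
  full <- dplyr::left_join(full, tables$descriptors, by = "compound_id")
  keep <- !is.na(full[[response]])
  out <- full[keep, c("compound_id", response, terms)]

  if (nrow(out) < length(terms) + 2) {
    abort(sprintf("Only %d compounds have non-missing %s; too few to fit %d predictor(s)",
                  nrow(out), response, length(terms)))
  }
  bad <- terms[vapply(out[terms], anyNA, logical(1))]
  if (length(bad)) {
    abort(sprintf("Term(s) undefined for some compounds (ratio with near-zero control RM): %s",
                  paste(bad, collapse = ", ")))
  }

  out <- tibble::as_tibble(out)
  attr(out, "response") <- response
  attr(out, "terms") <- terms
  attr(out, "phase") <- phase
  class(out) <- c("qsar_dataset", class(out))
  out
}

dataset_response <- function(data) attr(data, "response")
dataset_terms <- function(data) attr(data, "terms")
dataset_phase <- function(data) attr(data, "phase")
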