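#' Convert a retardation factor to the RM retention parameter
#'
#' The Bate-Smith--Westall transform `RM = log10(1/Rf - 1)` linearizes
#' thin-layer-chromatography retention for regression work: RM is 0 when a
#' spot travels half the solvent-front distance, positive for stronger
#' retention and negative for weaker.
#'
#' @param rf Retardation factor(s), strictly inside (0, 1).
#' @return RM value(s), finite and strictly decreasing in `rf`.
#' @seealso [rm_to_rf()] for the inverse.
#' @export
#' @examples
#' rf_to_rm(c(0.25, 0.5, 0.75))
rf_to_rm <- function(rf) {
  if (!is.numeric(rf) || any(!is.finite(rf)) || any(rf <= 0) || any(rf >= 1)) {
    abort("`rf` must be numeric with all values strictly between 0 and 1")
  }
  log10(1 / rf - 1)
}

#' Convert an RM retention parameter back to a retardation factor
#'
#' Inverse of [rf_to_rm()]: `Rf = 1 / (1 + 10^RM)`.
#'
#' @param rm Finite RM value(s).
#' @return Retardation factor(s) in (0, 1).
#' @export
#' @examples
#' rm_to_rf(0.308)
rm_to_rf <- function(rm) {
  if (!is.numeric(rm) || any(!is.finite(rm))) {
    abort("`rm` must be finite numeric")
  }
  1 / (1 + 10^rm)
}

# Below this, a control RM is treated as zero and ratio features as undefined.
RATIO_EPS <- 1e-9

#' Derive the biochromatographic interaction variables
#'
#' From a per-phase retention table, computes for every impregnated model
#' environment `Sk` (k = 1..7) the difference feature `C-Sk` = RM(C) -
#' RM(Sk) and the ratio feature `Sk/C` = RM(Sk) / RM(C). The difference
#' contrasts retention on the control plate against the amino-acid-analogue
#' plate, so it carries the specific ligand--"binding site" interaction;
#' the ratio expresses the same contrast on a relative scale. Raw `C` and
#' `S1`..`S7` columns are passed through unchanged.
#'
#' Ratio features are undefined (NA) where the control RM is numerically
#' zero (|RM(C)| < 1e-9); using such a feature as a model term errors at
#' [assemble_dataset()] time.
#'
#' @param retention A per-phase retention tibble from
#'   [read_retention_table()] (columns `compound_id`, `C`, `S1`..`S7`).
#' @return A tibble with columns `compound_id`, `C`, `S1`..`S7`,
#'   `C-S1`..`C-S7`, `S1/C`..`S7/C`; the `phase` attribute is carried
#'   over.
#' @export
#' @examples
#' tabs <- load_tables()
#' derive_features(tabs$retention$DS_A)[1, c("compound_id", "C-S4", "S4/C")]
derive_features <- function(retention) {
  missing_cols <- setdiff(c("compound_id", ENVIRONMENTS), names(retention))
  if (length(missing_cols)) {
    abort(sprintf("Retention table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(retention[c("compound_id", ENVIRONMENTS)])
  ctrl <- out$C
  ratio_ok <- abs(ctrl) >= RATIO_EPS
  for (k in 1:7) {
    out[[sprintf("C-S%d", k)]] <- ctrl - out[[paste0("S", k)]]
  }
  for (k in 1:7) {
    sk <- out[[paste0("S", k)]]
    ratio <- rep(NA_real_, length(sk))
    ratio[ratio_ok] <- sk[ratio_ok] / ctrl[ratio_ok]
    out[[sprintf("S%d/C", k)]] <- ratio
  }
  attr(out, "phase") <- attr(retention, "phase")
  out
}
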