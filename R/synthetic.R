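# Plausible generation scales for descriptor-like columns (location, scale),
# matching the magnitudes of the packaged descriptor table.
DESCRIPTOR_SCALES <- list(
  E_T = c(-90000, 25000), E_b = c(-4600, 900), dHf = c(10, 80),
  mu = c(3, 1.6), eps_HOMO = c(-8.5, 0.4), eps_LUMO = c(-0.3, 0.4),
  A_S = c(360, 70), V_m = c(330, 150), E_H = c(-4.5, 3.6),
  logP = c(0, 1.3), R_m = c(100, 18), alpha = c(36, 7),
  M_W = c(330, 70), Q_N = c(-0.26, 0.03), logD = c(1.8, 2.2),
  pKa = c(8, 1.9), PSA = c(46, 23), HD = c(1, 1), HA = c(4, 2)
)

# RM range typical of these TLC systems; also the scale of raw C/S columns.
RM_RANGE <- c(-0.5, 0.55)

#' Configure the synthetic-data generator
#'
#' Describes a synthetic study: how many compounds, which predictors the
#' response truly depends on (derived chromatographic features and/or
#' molecular descriptors), their marginal location/scale and pairwise
#' correlation, the true linear coefficients, the activity noise and the
#' per-activity missingness. The defaults emulate the agonist-potency
#' model of the packaged study: 20 compounds, pD2 generated from the
#' DS_A features `C-S4` and `C-S5` (feature correlation 0.48) with
#' coefficients (7.69, -15.89, 7.97), residual noise 0.37, and the study's
#' missing-activity pattern (pKi 1/20, pD2 7/20, pA2 4/20 missing).
#'
#' @param n_compounds Number of compounds.
#' @param response Which activity carries the linear signal.
#' @param phase Mobile phase whose retention table encodes the feature
#'   terms.
#' @param terms Named list: for each predictor, `c(location, scale)` of
#'   its marginal. Names of the form `C-Sk` are realized through the
#'   retention table (so the full pipeline, including
#'   [derive_features()], reproduces them); descriptor names are placed
#'   in the descriptor table.
#' @param family Marginal family for the predictors: `"normal"` or
#'   `"uniform"` (uniform spans location +/- scale) — the bounded option
#'   suits RM-like features.
#' @param correlation Pairwise predictor correlation matrix (or a single
#'   scalar used for every off-diagonal). Must be positive definite.
#' @param true_beta Numeric vector: intercept followed by one coefficient
#'   per term.
#' @param noise_sd Gaussian noise SD added to the response.
#' @param missing_rate Named rates in `[0, 1)` per activity.
#' @param seed Integer seed; generation is fully reproducible and leaves
#'   global RNG state untouched.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_compounds = 20,
                              response = "pD2",
                              phase = "DS_A",
                              terms = list(`C-S4` = c(0, 0.05),
                                           `C-S5` = c(0, 0.05)),
                              family = c("normal", "uniform"),
                              correlation = 0.48,
                              true_beta = c(7.69, -15.89, 7.97),
                              noise_sd = 0.37,
                              missing_rate = c(pKi = 0.05, pD2 = 0.35, pA2 = 0.20),
                              seed = 1) {
  family <- match.arg(family)
  response <- match.arg(response, ACTIVITIES)
  phase <- match.arg(phase, PHASES)
  k <- length(terms)
  if (is.null(names(terms)) || any(!nzchar(names(terms)))) {
    abort("`terms` must be a named list")
  }
  if (length(true_beta) != k + 1) {
    abort("`true_beta` must hold the intercept plus one coefficient per term")
  }
  if (is.matrix(correlation)) {
    R <- correlation
  } else {
    R <- matrix(correlation, k, k); diag(R) <- 1
  }
  if (k > 0 && (!isSymmetric(unname(R)) || any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 1e-10))) {
    abort("`correlation` must be a symmetric positive-definite matrix")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  mr <- missing_rate[ACTIVITIES]
  if (anyNA(mr) || any(mr < 0) || any(mr >= 1)) {
    abort("`missing_rate` needs a rate in [0, 1) for each of pKi, pD2, pA2")
  }
  structure(
    list(n_compounds = as.integer(n_compounds), response = response,
         phase = phase, terms = terms, family = family, correlation = R,
         true_beta = as.numeric(true_beta), noise_sd = noise_sd,
         missing_rate = setNames(as.numeric(mr), ACTIVITIES),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

feature_term_k <- function(name) {
  m <- regmatches(name, regexec("^C-S([1-7])$", name))[[1]]
  if (length(m)) as.integer(m[2]) else NA_integer_
}

#' Generate a synthetic study
#'
#' Draws predictor columns with the configured marginals and pairwise
#' correlation, builds the response as the true linear predictor plus
#' Gaussian noise, and packs everything into the same table layout as the
#' packaged study: feature terms named `C-Sk` are encoded into the
#' retention table of the configured phase (control RM uniform on the RM
#' scale, `Sk = C - feature`), all other environments and the other phase
#' get unstructured RM values, descriptor terms are placed verbatim in
#' the descriptor table and the remaining descriptors are drawn on
#' plausible scales (`HD`/`HA` as non-negative integers). Activities not
#' carrying the signal are drawn independently; each activity is then
#' masked at its configured missing rate. The output round-trips through
#' [write_tables()] / [load_tables()] unchanged, so the whole pipeline
#' runs on synthetic data exactly as on the study tables.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A `qsar_tables` object with attribute `truth` (the config and
#'   the realized predictor matrix).
#' @export
#' @examples
#' tabs <- simulate_tables(simulation_config(seed = 7))
#' fit_qsar(assemble_dataset(tabs, "pD2", c("C-S4", "C-S5"), "DS_A"))
simulate_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_tables_impl(config))
}

simulate_tables_impl <- function(config) {
  n <- config$n_compounds
  term_names <- names(config$terms)
  k <- length(term_names)

  # correlated predictors: Gaussian copula, then the requested marginals
  if (k > 0) {
    Z <- matrix(rnorm(n * k), n, k) %*% chol(config$correlation)
    X <- sapply(seq_len(k), function(j) {
      loc <- config$terms[[j]][1]; sc <- config$terms[[j]][2]
      if (config$family == "uniform") {
        loc + sc * (2 * stats::pnorm(Z[, j]) - 1)
      } else {
        loc + sc * Z[, j]
      }
    })
    X <- matrix(X, n, k, dimnames = list(NULL, term_names))
  } else {
    X <- matrix(numeric(0), n, 0)
  }

  make_retention <- function(phase, encode = FALSE) {
    ctrl <- runif(n, RM_RANGE[1], RM_RANGE[2])
    tab <- tibble::tibble(compound_id = seq_len(n), C = ctrl)
    for (kk in 1:7) tab[[paste0("S", kk)]] <- ctrl + rnorm(n, 0, 0.05)
    if (encode) {
      for (nm in term_names) {
        kk <- feature_term_k(nm)
        if (!is.na(kk)) tab[[paste0("S", kk)]] <- ctrl - X[, nm]
      }
    }
    attr(tab, "phase") <- phase
    tab
  }
  retention <- list(
    DS_A = make_retention("DS_A", encode = config$phase == "DS_A"),
    DS_B = make_retention("DS_B", encode = config$phase == "DS_B")
  )

  descriptors <- tibble::tibble(compound_id = seq_len(n))
  for (d in DESCRIPTORS) {
    sc <- DESCRIPTOR_SCALES[[d]]
    v <- rnorm(n, sc[1], sc[2])
    if (d %in% c("HD", "HA")) v <- pmax(0L, as.integer(round(v)))
    descriptors[[d]] <- v
  }
  for (nm in term_names) {
    if (is.na(feature_term_k(nm))) {
      if (!nm %in% DESCRIPTORS) {
        abort(sprintf("Term '%s' is neither a C-Sk feature nor a descriptor", nm))
      }
      v <- X[, nm]
      if (nm %in% c("HD", "HA")) v <- pmax(0L, as.integer(round(v)))
      descriptors[[nm]] <- v
    }
  }

  # signal response from the realized predictors (integer-rounded HD/HA
  # included as realized, so the linear model holds exactly in the tables)
  Xreal <- X
  for (nm in term_names) {
    if (is.na(feature_term_k(nm)) && nm %in% c("HD", "HA")) {
      Xreal[, nm] <- descriptors[[nm]]
    }
  }
  beta <- config$true_beta
  y <- beta[1] + (if (k > 0) drop(Xreal %*% beta[-1]) else 0) +
    rnorm(n, 0, config$noise_sd)

  activities <- tibble::tibble(compound_id = seq_len(n))
  for (a in ACTIVITIES) {
    activities[[a]] <- if (a == config$response) y else rnorm(n, 7, 1)
    drop_mask <- runif(n) < config$missing_rate[[a]]
    activities[[a]][drop_mask] <- NA_real_
  }

  structure(
    list(
      compounds = tibble::tibble(compound_id = seq_len(n),
                                 name = sprintf("synthetic-%02d", seq_len(n))),
      activities = activities,
      retention = retention,
      descriptors = descriptors
    ),
    class = "qsar_tables",
    truth = list(config = config, X = Xreal)
  )
}

#' Parameter-recovery experiment on synthetic studies
#'
#' Repeatedly generates a synthetic study (replicate r uses seed
#' `config$seed + r`), runs the full pipeline (assemble, OLS fit,
#' leave-one-out validation) with the true term set, and summarizes how
#' well the coefficients and predictive power are recovered.
#'
#' @param config A `sim_config`.
#' @param replicates Number of replicates (>= 1).
#' @return A `qsar_recovery`: per-coefficient tibble (`term`, `true`,
#'   `mean_estimate`, `bias`, `rmse`) with attributes `mean_Q2`,
#'   `mean_R2` and `replicates`.
#' @export
recovery_experiment <- function(config, replicates) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1)
  term_names <- names(config$terms)
  est <- matrix(NA_real_, replicates, length(term_names) + 1)
  q2 <- r2 <- numeric(replicates)
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    tabs <- simulate_tables(cfg)
    data <- assemble_dataset(tabs, config$response, term_names, config$phase)
    fit <- fit_qsar(data)
    est[r, ] <- fit$coefficients$estimate
    r2[r] <- fit$r.squared
    q2[r] <- loo_crossval(data)$Q2
  }
  out <- tibble::tibble(
    term = c("(Intercept)", term_names),
    true = config$true_beta,
    mean_estimate = colMeans(est),
    bias = colMeans(est) - config$true_beta,
    rmse = sqrt(colMeans(sweep(est, 2, config$true_beta)^2))
  )
  structure(out, mean_Q2 = mean(q2), mean_R2 = mean(r2),
            replicates = as.integer(replicates),
            class = c("qsar_recovery", class(out)))
}

#' @export
print.qsar_recovery <- function(x, ...) {
  cat(sprintf("<qsar_recovery> %d replicates; mean R2 = %.3f, mean Q2 = %.3f\n",
              attr(x, "replicates"), attr(x, "mean_R2"), attr(x, "mean_Q2")))
  NextMethod()
  invisible(x)
}

#' Read a simulation configuration from a key-value text file
#'
#' Plain-text `key = value` lines (`#` comments allowed). Recognized keys:
#' `n_compounds`, `response`, `phase`, `terms` (comma-separated names),
#' `locations`, `scales` (comma-separated, matching `terms`), `family`,
#' `correlation` (single off-diagonal value), `beta` (comma-separated,
#' intercept first), `noise_sd`, `missing_pki`, `missing_pd2`,
#' `missing_pa2`, `seed`. Unspecified keys keep the
#' [simulation_config()] defaults.
#'
#' @param path Path to the configuration file.
#' @return A `sim_config`.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  get <- function(key, default = NULL) if (key %in% keys) vals[match(key, keys)] else default
  split_num <- function(x) as.numeric(trimws(strsplit(x, ",")[[1]]))
  split_chr <- function(x) trimws(strsplit(x, ",")[[1]])

  base <- simulation_config()
  term_names <- if (!is.null(get("terms"))) split_chr(get("terms")) else names(base$terms)
  locations <- if (!is.null(get("locations"))) split_num(get("locations")) else rep(0, length(term_names))
  scales <- if (!is.null(get("scales"))) split_num(get("scales")) else rep(0.05, length(term_names))
  if (length(locations) != length(term_names) || length(scales) != length(term_names)) {
    abort("`locations` and `scales` must match `terms` in length")
  }
  terms <- setNames(purrr::map2(locations, scales, c), term_names)
  if (is.null(get("terms"))) terms <- base$terms

  simulation_config(
    n_compounds = as.integer(get("n_compounds", base$n_compounds)),
    response = get("response", base$response),
    phase = get("phase", base$phase),
    terms = terms,
    family = get("family", base$family),
    correlation = as.numeric(get("correlation", 0.48)),
    true_beta = if (!is.null(get("beta"))) split_num(get("beta")) else base$true_beta,
    noise_sd = as.numeric(get("noise_sd", base$noise_sd)),
    missing_rate = c(pKi = as.numeric(get("missing_pki", base$missing_rate[["pKi"]])),
                     pD2 = as.numeric(get("missing_pd2", base$missing_rate[["pD2"]])),
                     pA2 = as.numeric(get("missing_pa2", base$missing_rate[["pA2"]]))),
    seed = as.integer(get("seed", base$seed))
  )
}
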