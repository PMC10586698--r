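#' Severity scenario for synthetic cohorts
#'
#' Describes the world the generator draws from: each patient carries a
#' latent severity `z` in `[0, 1]` that (i) deforms the inter-parameter
#' correlation structure of their physiological time series, by convex
#' mixing `Sigma(z) = (1 - w(z)) C_healthy + w(z) C_sick` with mixing
#' weight `w(z) = z`, and (ii) drives the pre-transplant attributes through
#' linear (numeric) and logistic (binary) links; distractor attributes are
#' independent of `z`.  The default shapes mirror a 25-patient
#' three-cohort HSCT study: cohorts of 5 / 8 / 12 patients, `m = 11`
#' physiological parameters observed from about 8 days pre- to at most 18
#' days post-transplant with patient-specific truncation, and 30 encoded
#' pre-transplant attributes (4 numeric + 21 binary + one 6-level
#' categorical).
#'
#' @param cohort_sizes Named integer vector of patients per cohort.
#' @param m Number of physiological parameters.
#' @param n_range Integer range `[n_min, n_max]` for the per-patient row
#'   count (default 250-450: monitored vitals charted every one to two
#'   hours over a stay of one to four weeks, truncated by longevity).
#' @param time_range Observation window in days relative to transplant.
#' @param C_healthy,C_sick Unit-diagonal positive-definite `m x m`
#'   correlation matrices.  The defaults are AR(1)-type with coefficients
#'   0.15 and 0.8: for such matrices the adjacent-pair partial correlation
#'   equals the coefficient, so the healthy-to-sick contrast is stated
#'   directly in the quantity the graphical model reads.
#' @param ar_rho Optional AR(1) coefficient for the row process (0 =
#'   i.i.d. rows, the default; the method only uses inter-column
#'   correlation, so i.i.d. rows are the minimal sufficient emulation).
#' @param z Optional severity vector (length `sum(cohort_sizes)`); by
#'   default severities are equally spaced midpoints of `[0, 1]` randomly
#'   permuted across patients, so every cohort draw is spread over the
#'   whole range.
#' @param seed Master seed for the scenario.
#' @return Object of class `severity_scenario`.
#' @export
severity_scenario <- function(cohort_sizes = c(I = 5L, II = 8L, III = 12L),
                              m = 11L, n_range = c(250L, 450L),
                              time_range = c(-8, 18),
                              C_healthy = NULL, C_sick = NULL,
                              ar_rho = 0, z = NULL, seed = 1L) {
  # AR(1)-type correlation matrices state the contrast directly in partial
  # correlations (adjacent-pair partials equal the AR coefficient): weak
  # direct coupling between adjacent organ-system parameters in stable
  # patients vs. strong coupled derangement under disease.
  if (is.null(C_healthy)) C_healthy <- stats::toeplitz(0.15^(0:(m - 1)))
  if (is.null(C_sick)) C_sick <- stats::toeplitz(0.8^(0:(m - 1)))
  check_corr <- function(C, nm) {
    if (!isTRUE(all.equal(C, t(C))) || any(abs(diag(C) - 1) > 1e-12))
      stop(nm, " must be symmetric with unit diagonal")
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop(nm, " must be positive definite")
  }
  check_corr(C_healthy, "C_healthy"); check_corr(C_sick, "C_sick")
  n_p <- sum(cohort_sizes)
  if (is.null(z)) {
    z <- withr_seed(derive_seed(seed, "z"),
                    sample((seq_len(n_p) - 0.5) / n_p))
  }
  if (any(z < 0 | z > 1)) stop("severities z must lie in [0, 1]")
  # attribute links: value = alpha + beta * z + N(0, sd^2) for numeric,
  # P(1) = plogis(alpha + beta * z) for binary; beta = 0 marks a distractor
  numeric_links <- data.frame(
    name = c("age", "ferritin_pre", "crp_pre", "weight"),
    alpha = c(40, 500, 10, 70), beta = c(20, 900, 40, 0),
    sd = c(8, 150, 8, 10), stringsAsFactors = FALSE)
  binary_links <- data.frame(
    name = c("liver_disease", "hepatic_dysfunction", "pulmonary_dysfunction",
             "cardiac_disease", "diabetes", "hypertension", "cmv_positive",
             "cmv_reactive", "hla_mismatch", "abo_mismatch",
             "gender_mismatch", "relapsed", "azathioprine",
             "mercaptopurine", "myelotarg", "cytarabine", "male",
             "prior_radiation", "renal_dysfunction", "obesity",
             "novel_condition"),
    alpha = c(-2, -2.5, -2, -1.5, -1.5, -1, -1, -2, -1, -1.5,
              -1, -1.5, -2, -2, -2.5, -1.5, 0, -2, -2.5, -1.5, -Inf),
    beta = c(4, 4, 3, 2, 0, 0, 2, 2, 2, 0,
             0, 3, 0, 0, 0, 0, 0, 0, 2, 0, 0),
    stringsAsFactors = FALSE)
  cancer_levels <- c("Other", "ALL", "AML", "Aplastic", "CML",
                     "Myelofibrosis")
  structure(list(cohort_sizes = cohort_sizes, m = m, n_range = n_range,
                 time_range = time_range, C_healthy = C_healthy,
                 C_sick = C_sick, ar_rho = ar_rho, z = z,
                 numeric_links = numeric_links, binary_links = binary_links,
                 cancer_levels = cancer_levels, seed = as.integer(seed)),
            class = "severity_scenario")
}

#' Mixed correlation matrix at severity z
#'
#' Convex mixture `(1 - z) C_healthy + z C_sick`; a convex mixture of
#' unit-diagonal PD correlation matrices is again one, which is asserted.
#'
#' @param scenario A [severity_scenario()].
#' @param z Severity in `[0, 1]`.
#' @return `m x m` correlation matrix.
#' @export
mix_correlation <- function(scenario, z) {
  S <- (1 - z) * scenario$C_healthy + z * scenario$C_sick
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(min(ev) > 0, all(abs(diag(S) - 1) < 1e-12))
  S
}

# Raw (un-encoded) attribute rows for severities z_vec; novel flags mark
# patients whose `novel_condition` indicator is forced to 1.
gen_raw_attributes <- function(scenario, z_vec, seed, novel = NULL,
                               noise = TRUE) {
  n <- length(z_vec)
  if (is.null(novel)) novel <- rep(FALSE, n)
  withr_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(scenario$numeric_links))) {
      lk <- scenario$numeric_links[i, ]
      mu <- lk$alpha + lk$beta * z_vec
      out[[lk$name]] <- if (noise) mu + stats::rnorm(n, 0, lk$sd) else mu
    }
    for (i in seq_len(nrow(scenario$binary_links))) {
      lk <- scenario$binary_links[i, ]
      p <- stats::plogis(lk$alpha + lk$beta * z_vec)
      out[[lk$name]] <- if (noise) stats::rbinom(n, 1, p)
                        else as.numeric(p > 0.5)
    }
    out[["cancer_type"]] <- if (noise)
      sample(scenario$cancer_levels, n, replace = TRUE,
             prob = c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1))
    else rep(scenario$cancer_levels[1], n)
    out[["novel_condition"]][novel] <- 1
    as.data.frame(out, stringsAsFactors = FALSE)
  })
}

# One patient's synthetic physiological record.
gen_patient_ts <- function(scenario, z, patient_id, cohort_id, seed) {
  withr_seed(seed, {
    n_t <- scenario$n_range[1] +
      sample.int(scenario$n_range[2] - scenario$n_range[1] + 1L, 1L) - 1L
    times <- sort(stats::runif(n_t, scenario$time_range[1],
                               scenario$time_range[2]))
    L <- chol(mix_correlation(scenario, z))
    eps <- matrix(stats::rnorm(n_t * scenario$m), n_t) %*% L
    rho <- scenario$ar_rho
    x <- eps
    if (rho != 0) {
      for (t in 2:n_t) x[t, ] <- rho * x[t - 1, ] + sqrt(1 - rho^2) * eps[t, ]
    }
    colnames(x) <- sprintf("phys_%02d", seq_len(scenario$m))
    patient_ts(patient_id, cohort_id, times, x)
  })
}

#' Simulate a synthetic multi-cohort study
#'
#' Draws, for every patient, a physiological time series with inter-column
#' correlation `Sigma(z_j)` (i.i.d. rows by default, optional AR(1)) and a
#' mixed-type pre-transplant attribute row linked to `z_j`; fully
#' reproducible from the scenario seed via per-patient derived streams.
#'
#' @param scenario A [severity_scenario()].
#' @return List with elements `ts` (named list of [patient_ts]), `table`
#'   (encoded `pretransplant_table`), `truth` (data.frame `patient_id`,
#'   `cohort_id`, `z`), and `scenario`.
#' @export
simulate_cohort <- function(scenario) {
  sizes <- scenario$cohort_sizes
  cohorts <- rep(names(sizes), sizes)
  n <- sum(sizes)
  ids <- unlist(lapply(names(sizes), function(co)
    sprintf("%s-%02d", co, seq_len(sizes[[co]]))))
  ts <- vector("list", n); names(ts) <- ids
  for (j in seq_len(n)) {
    ts[[j]] <- gen_patient_ts(scenario, scenario$z[j], ids[j], cohorts[j],
                              derive_seed(scenario$seed, paste0("ts:", ids[j])))
  }
  raw <- gen_raw_attributes(scenario, scenario$z,
                            derive_seed(scenario$seed, "attrs"))
  raw <- cbind(patient_id = ids, raw, stringsAsFactors = FALSE)
  table <- encode_pretransplant(raw,
    levels_map = list(cancer_type = scenario$cancer_levels))
  truth <- data.frame(patient_id = ids, cohort_id = cohorts,
                      z = scenario$z, stringsAsFactors = FALSE)
  list(ts = ts, table = table, truth = truth, scenario = scenario)
}

#' Simulate a prospective patient's pre-transplant vector
#'
#' Generates one raw attribute row at severity `z_test`.  With
#' `include_novel = TRUE` the `novel_condition` indicator—which is 0 for
#' every training patient—is set to 1, so exactly one encoded column
#' differs systematically from the whole training cohort (the
#' extrapolation setting: a condition no retrospective patient had).
#'
#' @param scenario A [severity_scenario()].
#' @param z_test Severity of the test patient.
#' @param include_novel Force the novel binary attribute to 1.
#' @param noise With `FALSE`, numeric attributes equal their link means
#'   `alpha + beta * z_test` and binaries their most probable value.
#' @param seed Integer seed.
#' @return One-row data.frame of raw attributes (encode with
#'   [encode_new_patient()]).
#' @export
simulate_test_patient <- function(scenario, z_test, include_novel = FALSE,
                                  noise = TRUE, seed = NULL) {
  if (is.null(seed)) seed <- derive_seed(scenario$seed, paste0("test:", z_test))
  gen_raw_attributes(scenario, z_test, seed, novel = include_novel,
                     noise = noise)
}

#' Write a simulated cohort to a directory of plain-text artifacts
#'
#' One CSV per patient time series, a raw attribute CSV, a JSON manifest
#' and a JSON truth record — the on-disk layout the command-line interface
#' operates on.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(sim$ts))
  for (j in seq_along(sim$ts)) {
    files[j] <- paste0(sim$ts[[j]]$patient_id, ".csv")
    write_time_series(sim$ts[[j]], file.path(dir, files[j]))
  }
  manifest <- data.frame(
    patient_id = sim$truth$patient_id, cohort_id = sim$truth$cohort_id,
    file = files,
    is_reference = !duplicated(sim$truth$cohort_id),
    stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(dir, "manifest.json"))
  write_pretransplant(sim$table$raw_attributes_with_ids %||%
                        cbind(patient_id = sim$truth$patient_id,
                              sim$table$raw_attributes),
                      file.path(dir, "pretransplant.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
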