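#' Shortest 95% highest-density interval of a sample
#'
#' @param draws Numeric vector of posterior draws.
#' @param prob Coverage, default 0.95.
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  if (n < 2) return(c(x[1], x[1]))
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Case-consistent prior mean for a score component
#'
#' The score model sets `|s_j - 1| = delta_1j` and
#' `delta_ij = |delta_1j - delta_1i|`.  Solving for `s_j` in terms of a
#' comparator patient's proposed score `s_i` yields, case by case on which
#' side of 1 the two proposals lie and on the ordering of the observed
#' reference distances:
#' \itemize{
#'   \item both below 1: `s_i + delta_ij` if `delta_1i > delta_1j`,
#'     else `s_i - delta_ij`;
#'   \item both at/above 1: `s_i - delta_ij` if `delta_1i > delta_1j`,
#'     else `s_i + delta_ij`;
#'   \item `s_j >= 1 > s_i`: `2 - s_i + delta_ij` if
#'     `delta_1j > delta_1i`, else `2 - s_i - delta_ij`;
#'   \item `s_j < 1 <= s_i`: `2 - s_i - delta_ij` if
#'     `delta_1j > delta_1i`, else `2 - s_i + delta_ij`.
#' }
#' The mixed-side expressions follow from the same `|s - 1|` algebra as the
#' same-side ones (substitute `delta_1j = |s_j - 1|` and eliminate); they
#' are an interpretation forced by the model's absolute-value structure.
#'
#' @param s_j_prop Proposed score of the updated patient (scalar).
#' @param s_i_prop Proposed/current scores of comparator patients (vector).
#' @param delta_1j Observed distance of patient j to the reference (scalar).
#' @param delta_1i Distances of the comparators to the reference (vector).
#' @param delta_ij Distances between j and the comparators (vector).
#' @return Vector of prior means, one per comparator.
#' @export
case_prior_mean <- function(s_j_prop, s_i_prop, delta_1j, delta_1i, delta_ij) {
  if (any(c(delta_1j, delta_1i, delta_ij) < 0)) stop("distances must be >= 0")
  j_up <- s_j_prop >= 1
  i_up <- s_i_prop >= 1
  case1 <- delta_1i > delta_1j            # same-side case split
  jdom <- delta_1j > delta_1i             # mixed-side case split
  same_mean <- ifelse(xor(j_up, case1), s_i_prop + delta_ij,
                      s_i_prop - delta_ij)
  mixed_sign <- ifelse(xor(j_up, jdom), -delta_ij, delta_ij)
  mixed_mean <- 2 - s_i_prop + mixed_sign
  ifelse(i_up == j_up, same_mean, mixed_mean)
}

#' Initialise scores by one-dimensional embedding of the distance matrix
#'
#' Classical MDS restricted to one dimension recovers a signed coordinate
#' for each patient up to reflection; anchoring the reference at 1 gives a
#' starting configuration whose pairwise gaps already honour the distances.
#' The reflection (which side of the reference the cohort falls on) is the
#' one bit the distances cannot supply; it is fixed by `side` hints when
#' given, and arbitrary otherwise.
#'
#' @param delta Symmetric distance matrix.
#' @param ref Reference index.
#' @param side Optional character vector (length `ncol(delta)`) of
#'   `"above"`, `"below"` or `NA` severity hints relative to the reference.
#' @return Numeric vector of initial scores with `[ref] == 1`.
#' @keywords internal
init_scores_mds <- function(delta, ref, side = NULL) {
  n <- ncol(delta)
  x <- tryCatch(suppressWarnings(as.numeric(stats::cmdscale(delta, k = 1))),
                error = function(e) rep(0, n))
  if (length(x) != n || !all(is.finite(x))) x <- rep(0, n)
  s <- 1 + (x - x[ref])
  if (!is.null(side)) {
    want_up <- side == "above"
    known <- !is.na(side)
    if (any(known)) {
      agree <- sum((s[known] >= 1) == want_up[known])
      if (agree < sum(known) / 2) s <- 2 - s   # reflect whole configuration
      bad <- known & ((s >= 1) != (side == "above"))
      s[bad] <- 2 - s[bad]                     # per-patient reflection
    }
  }
  s[ref] <- 1
  s
}

#' Learn relative scores from a distance matrix by Metropolis-Hastings
#'
#' The reference patient is fixed at score 1.  Every other patient's score
#' gets, per sweep, a Normal random-walk proposal; the log target for
#' component `s_j` is the Normal likelihood of the observed reference
#' distance, `log N(delta_1j ; |s_j - 1|, likelihood_sd^2)`, plus the sum
#' over all comparators `i != j` (excluding the reference) of
#' `log N(s_j ; case_prior_mean(...), prior_sd^2)`.  Proposals are accepted
#' by the standard symmetric-proposal ratio.
#'
#' The target is invariant under reflecting the whole configuration about
#' 1; which branch a patient settles on is decided by the initial
#' configuration (a 1-d embedding of the distances, see
#' [init_scores_mds()]) and by any `side` hints, mirroring how clinician
#' severity orderings anchor reference patients across cohorts.  `side`
#' hints act as hard support constraints (proposals on the wrong side of 1
#' are rejected).
#'
#' @param dist A `distance_matrix` (or plain symmetric matrix).
#' @param reference Index or patient id of the reference (score 1).
#' @param config A [run_config()]; `config$mcmc` supplies chain length,
#'   burn-in, proposal sd, likelihood sd and prior sd `v`.
#' @param side Optional named character vector of `"above"` / `"below"`
#'   hints (names = patient ids) or unnamed vector of length `N_p`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param prior_mode `"product"` (default; prior multiplies over all
#'   comparators) or `"single"` (one uniformly chosen comparator per
#'   update, for large cohorts).
#' @return Object of class `score_posterior`: `draws` (retained sweeps x
#'   `N_p`), `mean`, `hpd` (`N_p x 2`), `reference`, `patient_ids`,
#'   `acceptance` rates.
#' @export
learn_scores <- function(dist, reference = 1L, config = run_config(),
                         side = NULL, seed = NULL,
                         prior_mode = c("product", "single")) {
  prior_mode <- match.arg(prior_mode)
  delta <- if (inherits(dist, "distance_matrix")) dist$delta else as.matrix(dist)
  n <- ncol(delta)
  ids <- colnames(delta)
  if (is.null(ids)) ids <- paste0("P", seq_len(n))
  if (is.character(reference)) reference <- match(reference, ids)
  if (is.na(reference) || reference < 1 || reference > n)
    stop("invalid reference patient")
  mc <- config$mcmc
  if (mc$likelihood_sd <= 0 || mc$prior_sd <= 0)
    stop("likelihood and prior sds must be > 0")
  if (!is.null(side)) {
    if (!is.null(names(side))) {
      full <- rep(NA_character_, n)
      full[match(names(side), ids)] <- unname(side)
      side <- full
    }
    if (length(side) != n) stop("side hints must cover all patients")
  }
  if (is.null(seed)) seed <- derive_seed(config$seed, "scores")

  d1 <- delta[reference, ]
  others <- setdiff(seq_len(n), reference)
  s <- init_scores_mds(delta, reference, side)
  n_sweeps <- mc$n_sweeps; burn <- mc$burn_in
  if (burn >= n_sweeps) stop("burn_in must be smaller than n_sweeps")
  draws <- matrix(NA_real_, n_sweeps - burn, n,
                  dimnames = list(NULL, ids))
  acc <- stats::setNames(numeric(n), ids)

  log_target <- function(j, sj, comp) {
    mu <- case_prior_mean(sj, s[comp], d1[j], d1[comp], delta[j, comp])
    stats::dnorm(d1[j], abs(sj - 1), mc$likelihood_sd, log = TRUE) +
      sum(stats::dnorm(sj, mu, mc$prior_sd, log = TRUE))
  }

  withr_seed(seed, {
    for (t in seq_len(n_sweeps)) {
      for (j in others) {
        comp <- if (prior_mode == "product") setdiff(others, j) else {
          pool <- setdiff(others, j)
          if (length(pool)) pool[sample.int(length(pool), 1L)] else integer(0)
        }
        prop <- s[j] + stats::rnorm(1, 0, mc$proposal_sd)
        if (!is.null(side) && !is.na(side[j])) {
          if (side[j] == "above" && prop < 1) next
          if (side[j] == "below" && prop >= 1) next
        }
        lr <- log_target(j, prop, comp) - log_target(j, s[j], comp)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          s[j] <- prop
          acc[j] <- acc[j] + 1
        }
      }
      if (t > burn) draws[t - burn, ] <- s
    }
  })
  hpd <- t(apply(draws, 2, hpd_interval))
  colnames(hpd) <- c("lower", "upper")
  means <- colMeans(draws)
  means[reference] <- 1
  hpd[reference, ] <- NA_real_
  structure(list(draws = draws, mean = means, hpd = hpd,
                 reference = reference, patient_ids = ids,
                 acceptance = acc / n_sweeps),
            class = "score_posterior")
}

#' @export
print.score_posterior <- function(x, ...) {
  cat("<score_posterior> ", length(x$mean), " patients, ",
      nrow(x$draws), " retained sweeps; reference = ",
      x$patient_ids[x$reference], "\n", sep = "")
  invisible(x)
}

#' Minimal reference-only score posterior
#'
#' Convenience constructor for a cohort whose only available score is the
#' reference's assigned value of 1 (no draws, no uncertainty), e.g. when
#' aligning published summaries.
#'
#' @param patient_id Reference patient id.
#' @return A `score_posterior` with one patient.
#' @export
reference_only_posterior <- function(patient_id) {
  structure(list(draws = matrix(1, 1, 1, dimnames = list(NULL, patient_id)),
                 mean = stats::setNames(1, patient_id),
                 hpd = matrix(NA_real_, 1, 2,
                              dimnames = list(patient_id, c("lower", "upper"))),
                 reference = 1L, patient_ids = patient_id,
                 acceptance = stats::setNames(0, patient_id)),
            class = "score_posterior")
}

#' Align per-cohort score posteriors to a universal reference
#'
#' Each cohort's scores were learnt relative to its own reference (score
#' 1).  Given the inter-graph distance `d` between a cohort's reference and
#' the universal reference, the cohort reference's aligned score is
#' `1 + d` when clinicians identify that reference as more severe than the
#' universal reference, and `1 - d` when less severe; every score, draw and
#' HPD bound in the cohort is shifted by the same `+d` or `-d`.  The
#' universal cohort is unshifted.  Shifted cohort references carry no
#' uncertainty (their HPD is reported `NA`), and neither does the universal
#' reference's assigned score of 1.
#'
#' @param posteriors Named list of `score_posterior`s, one per cohort
#'   (names = cohort ids).
#' @param universal_cohort Cohort id whose reference is the universal
#'   reference patient.
#' @param alignments Data.frame with one row per non-universal cohort:
#'   columns `cohort_id`, `d` (nonnegative inter-reference distance) and
#'   `more_severe` (logical: is this cohort's reference more severe than
#'   the universal reference?).
#' @return Object of class `aligned_scores`: a `table` data.frame
#'   (`patient_id`, `cohort_id`, `mean`, `hpd_lower`, `hpd_upper`,
#'   `is_reference`, `shift`), per-cohort `shifts`, and shifted `draws`.
#' @export
align_cohorts <- function(posteriors, universal_cohort, alignments = NULL) {
  if (!universal_cohort %in% names(posteriors))
    stop("universal cohort '", universal_cohort, "' not among posteriors")
  shifts <- stats::setNames(rep(NA_real_, length(posteriors)),
                            names(posteriors))
  shifts[universal_cohort] <- 0
  for (co in setdiff(names(posteriors), universal_cohort)) {
    row <- alignments[alignments$cohort_id == co, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("missing alignment spec (distance + severity ordering) for ",
           "cohort '", co, "'")
    if (is.na(row$more_severe))
      stop("missing severity ordering for cohort '", co, "'")
    if (row$d < 0) stop("inter-reference distance must be >= 0")
    shifts[co] <- if (isTRUE(row$more_severe)) row$d else -row$d
  }
  tabs <- list(); draws <- list()
  for (co in names(posteriors)) {
    po <- posteriors[[co]]
    sh <- shifts[co]
    is_ref <- seq_along(po$patient_ids) == po$reference
    mean_sh <- po$mean + sh
    hpd_sh <- po$hpd + sh
    hpd_sh[is_ref, ] <- NA_real_   # references carry no uncertainty
    tabs[[co]] <- data.frame(
      patient_id = po$patient_ids, cohort_id = co,
      mean = unname(mean_sh),
      hpd_lower = unname(hpd_sh[, 1]), hpd_upper = unname(hpd_sh[, 2]),
      is_reference = is_ref, shift = unname(sh),
      row.names = NULL, stringsAsFactors = FALSE)
    draws[[co]] <- po$draws + sh
  }
  structure(list(table = do.call(rbind, c(tabs, make.row.names = FALSE)),
                 shifts = shifts, draws = draws,
                 universal_cohort = universal_cohort),
            class = "aligned_scores")
}

#' @export
print.aligned_scores <- function(x, ...) {
  cat("<aligned_scores> ", nrow(x$table), " patients across ",
      length(x$shifts), " cohorts (universal: ", x$universal_cohort, ")\n",
      sep = "")
  print(x$table, digits = 3)
  invisible(x)
}

#' Classify VOD status from a learnt score
#'
#' A learnt mean score of at most 0.11 implies avoidance of VOD onset; any
#' mean above 0.11 is classified as VOD-positive.  In the
#' uncertainty-aware mode the upper 95% HPD bound is compared against 0.31
#' instead (scores can maximally reach 0.31 for a patient to remain
#' VOD-free once uncertainty is taken into account).
#'
#' @param mean_score Numeric vector of mean scores.
#' @param upper_hpd Optional numeric vector of upper 95% HPD bounds
#'   (required for `mode = "uncertainty"`).
#' @param thresholds List with elements `mean` (default 0.11) and
#'   `upper_hpd` (default 0.31).
#' @param mode `"mean"` (default) or `"uncertainty"`.
#' @return Character vector of `"Y"` / `"N"` labels.
#' @export
classify_status <- function(mean_score, upper_hpd = NULL,
                            thresholds = list(mean = 0.11, upper_hpd = 0.31),
                            mode = c("mean", "uncertainty")) {
  mode <- match.arg(mode)
  if (mode == "mean") {
    ifelse(mean_score > thresholds$mean, "Y", "N")
  } else {
    if (is.null(upper_hpd)) stop("uncertainty mode needs upper HPD bounds")
    ifelse(upper_hpd > thresholds$upper_hpd, "Y", "N")
  }
}
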