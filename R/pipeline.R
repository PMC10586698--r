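#' Run the full retrospective-scoring pipeline
#'
#' Convenience wrapper covering the score-learning half of the method:
#' per-patient partial correlations, graph chains sampled with common
#' random-number streams, the cohort-wide distance matrix, per-cohort
#' Metropolis-Hastings score inference, and alignment of all cohorts to a
#' universal reference through inter-reference distances and clinician
#' severity orderings.
#'
#' @param ts Named list of [patient_ts] objects (all patients, all
#'   cohorts).
#' @param references Named character vector: cohort id -> reference
#'   patient id (within-cohort score 1).
#' @param universal_cohort Cohort whose reference anchors the common
#'   scale.
#' @param ref_more_severe Named logical vector over the non-universal
#'   cohorts: is that cohort's reference more severe than the universal
#'   reference?  (Clinician-supplied ordering; a missing entry is an
#'   error at alignment time.)
#' @param config A [run_config()].
#' @param side Optional named character vector of `"above"`/`"below"`
#'   severity hints for non-reference patients (relative to their cohort
#'   reference), passed to [learn_scores()].
#' @return List with `chains`, `dist` (full `distance_matrix`),
#'   `posteriors` (per cohort), `aligned` ([align_cohorts()] result) and
#'   `graphs` (per-patient `graphical_model` at `config$tau`).
#' @export
vod_pipeline <- function(ts, references, universal_cohort,
                         ref_more_severe = NULL, config = run_config(),
                         side = NULL) {
  ids <- vapply(ts, function(x) x$patient_id, character(1))
  cohorts <- vapply(ts, function(x) x$cohort_id, character(1))
  names(ts) <- ids
  chain_seed <- derive_seed(config$seed, "chains")   # common streams
  chains <- lapply(ts, function(x)
    sample_graph_chain(correlation_matrix(x), n_iter = config$n_iter,
                       seed = chain_seed, stream_policy = "common"))
  graphs <- lapply(chains, extract_graphical_model, tau = config$tau)
  dist <- distance_matrix(chains)
  posteriors <- list()
  for (co in unique(cohorts)) {
    sub <- ids[cohorts == co]
    ref <- references[[co]]
    if (is.null(ref) || !ref %in% sub)
      stop("no valid reference for cohort '", co, "'")
    posteriors[[co]] <- learn_scores(
      dist$delta[sub, sub, drop = FALSE], reference = ref, config = config,
      side = side[intersect(names(side), sub)],
      seed = derive_seed(config$seed, paste0("scores:", co)))
  }
  uref <- references[[universal_cohort]]
  other <- setdiff(unique(cohorts), universal_cohort)
  alignments <- NULL
  if (length(other)) {
    alignments <- data.frame(
      cohort_id = other,
      d = vapply(other, function(co) dist$delta[references[[co]], uref],
                 numeric(1)),
      more_severe = vapply(other, function(co) {
        v <- ref_more_severe[[co]]
        if (is.null(v)) NA else v
      }, logical(1)),
      stringsAsFactors = FALSE)
  }
  aligned <- align_cohorts(posteriors, universal_cohort, alignments)
  list(chains = chains, graphs = graphs, dist = dist,
       posteriors = posteriors, aligned = aligned)
}
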