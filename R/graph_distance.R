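#' Scale log-posterior traces to a common maximum
#'
#' The per-iteration log posteriors of every patient's graph chain are
#' shifted by the cohort-wide scale
#' `B = max over patients and iterations of log_post`, giving traces
#' `u_i[q] = log_post_i[q] - B <= 0`.  B is computed once over the whole
#' run, so differences of traces are invariant to any global additive shift
#' of the log posteriors.
#'
#' @param chains List of `graph_chain` objects sharing one `n_iter`.
#' @return Object of class `log_post_traces`: fields `u` (list of numeric
#'   vectors), `B`, `n_iter`, `patient_ids` (names of `chains`, if any).
#' @export
scale_traces <- function(chains) {
  if (inherits(chains, "graph_chain")) chains <- list(chains)
  ni <- vapply(chains, function(ch) ch$n_iter, integer(1))
  if (length(unique(ni)) != 1L)
    stop("all chains must share a common n_iter; got ",
         paste(unique(ni), collapse = ", "))
  B <- max(vapply(chains, function(ch) max(ch$log_post), numeric(1)))
  u <- lapply(chains, function(ch) ch$log_post - B)
  structure(list(u = u, B = B, n_iter = ni[1],
                 patient_ids = names(chains)),
            class = "log_post_traces")
}

#' Discretised Hellinger distance between two graph posteriors
#'
#' Root-mean-square difference of two patients' scaled log-posterior
#' traces, paired by iteration:
#' `delta_ij = sqrt( sum_q (u_i[q] - u_j[q])^2 / N_iter )`.
#' This is the distance the score model is built on; it is an L2 distance
#' between trace vectors, hence nonnegative, symmetric and triangular.
#'
#' @param u_i,u_j Numeric trace vectors of equal length (iteration-paired).
#' @return Single nonnegative number.
#' @export
hellinger_distance <- function(u_i, u_j) {
  if (length(u_i) != length(u_j))
    stop("trace length mismatch: ", length(u_i), " vs ", length(u_j))
  sqrt(mean((u_i - u_j)^2))
}

#' Cohort distance matrix
#'
#' Assembles all pairwise [hellinger_distance()]s from the patients'
#' chains after common [scale_traces()] scaling.  With the default
#' common-random-number streams (same chain seed for every patient),
#' identical time series give exactly zero distance, so delta reflects
#' structural difference rather than sampler noise.
#'
#' @param chains Named list of `graph_chain`s (one per patient, common
#'   `n_iter`; use a common seed for `stream_policy = "common"` semantics).
#' @return Object of class `distance_matrix`: `delta` (symmetric `N_p x N_p`
#'   matrix with zero diagonal, dimnames = patient ids) and the scale `B`.
#' @export
distance_matrix <- function(chains) {
  tr <- scale_traces(chains)
  n <- length(tr$u)
  delta <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      delta[i, j] <- delta[j, i] <- hellinger_distance(tr$u[[i]], tr$u[[j]])
    }
  }
  ids <- tr$patient_ids
  if (!is.null(ids)) dimnames(delta) <- list(ids, ids)
  structure(list(delta = delta, B = tr$B), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix> ", ncol(x$delta), " patients, B = ",
      signif(x$B, 6), "\n", sep = "")
  invisible(x)
}
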