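#' Correlation, precision and partial-correlation structure of a record
#'
#' Computes the Pearson inter-column correlation matrix Sigma of a patient's
#' time series, its precision matrix psi = Sigma^-1, and the partial
#' correlation matrix R with off-diagonal entries
#' `R[k,l] = -psi[k,l] / sqrt(psi[k,k] * psi[l,l])` and unit diagonal.
#' Partial correlations condition each pair of physiological parameters on
#' all the others, so they isolate direct association.
#'
#' When the smallest eigenvalue of Sigma falls below `1e-8` (short series,
#' m close to n_t), Sigma is shrunk to `(Sigma + ridge*I) / (1 + ridge)`
#' before inversion; this preserves the unit diagonal.
#'
#' @param ts A [patient_ts] (or a plain numeric matrix).
#' @param ridge Nonnegative ridge applied only when Sigma is near-singular
#'   (default `1e-6`).
#' @param method Correlation estimator, `"pearson"` (default) or
#'   `"spearman"`.
#' @return An object of class `corr_structure` with fields `sigma`, `psi`,
#'   `r`, `ridged` (logical) and `column_names`.
#' @export
correlation_matrix <- function(ts, ridge = 1e-6, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- if (inherits(ts, "patient_ts")) ts$values else as.matrix(ts)
  if (nrow(x) < 3L) stop("need at least 3 rows to estimate correlations")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "),
         "; correlation undefined")
  }
  sigma <- stats::cor(x, method = method)
  ridged <- FALSE
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    if (ridge <= 0) stop("correlation matrix near-singular and ridge = 0")
    sigma <- (sigma + ridge * diag(ncol(sigma))) / (1 + ridge)
    ridged <- TRUE
    message("applied ridge ", ridge, " to a near-singular correlation matrix")
  }
  psi <- tryCatch(solve(sigma), error = function(e)
    stop("precision matrix inversion failed even after ridge: ",
         conditionMessage(e)))
  dpsi <- sqrt(diag(psi))
  r <- -psi / tcrossprod(dpsi)
  diag(r) <- 1
  r <- (r + t(r)) / 2
  structure(list(sigma = sigma, psi = psi, r = r, ridged = ridged,
                 column_names = colnames(x)),
            class = "corr_structure")
}

#' Variance-marginalised edge density f(S)
#'
#' Unnormalised marginal density of the separation `S = |G - |r||` between
#' an edge state G in \{0,1\} and the absolute partial correlation |r|,
#' after marginalising the Normal observation variance upsilon over its
#' Uniform(0,1) prior:
#' `f(S) = sqrt(2/pi) exp(-S^2/2) - S * erfc(S / sqrt(2))`,
#' which equals `integral_0^1 (2 pi v)^{-1/2} exp(-S^2 / (2v)) dv`.
#'
#' @param s Numeric vector of separations in `[0, 1]`.
#' @return `f(s)`, vectorised.
#' @export
edge_marginal_f <- function(s) {
  if (any(s < 0 | s > 1)) stop("separation S must lie in [0, 1]")
  # erfc(s/sqrt(2)) == 2 * pnorm(s, lower.tail = FALSE)
  sqrt(2 / pi) * exp(-s^2 / 2) - s * 2 * stats::pnorm(s, lower.tail = FALSE)
}

#' Closed-form posterior probability of an edge
#'
#' With a Bernoulli(0.5) prior on the edge state and the marginalised
#' density [edge_marginal_f()], the posterior that the edge exists given
#' `|r| = r_abs` is `f(1 - r_abs) / (f(r_abs) + f(1 - r_abs))`; the
#' denominator realises the normaliser K over G in \{0,1\}.  The function is
#' strictly increasing in `r_abs`, equals 0.5 exactly at `r_abs = 0.5`, and
#' satisfies the complement symmetry `p(r) + p(1 - r) = 1`.
#'
#' @param r_abs Numeric vector of absolute partial correlations in `[0,1]`.
#' @return Posterior edge probabilities, vectorised.
#' @export
edge_marginal_probability <- function(r_abs) {
  if (any(r_abs < 0 | r_abs > 1)) stop("|r| must lie in [0, 1]")
  f1 <- edge_marginal_f(1 - r_abs)   # separation when G = 1
  f0 <- edge_marginal_f(r_abs)       # separation when G = 0
  f1 / (f0 + f1)
}

#' Sample a chain of soft-random-geometric graphs
#'
#' Draws `n_iter` binary graphs over the `m(m-1)/2` nodal pairs.  Each edge
#' is an independent two-point variable with success probability
#' [edge_marginal_probability()] of its absolute partial correlation, so
#' inverse-CDF sampling (uniform < p) is distributionally identical to
#' rejection-sampling the closed-form marginal; `sampler = "rejection"`
#' provides the literal accept/reject construction against the
#' Bernoulli(0.5) prior for fidelity demonstrations.
#'
#' The per-iteration log posterior
#' `log_post[q] = sum_{k<l} log m(g_q[k,l] | r[k,l])`
#' is stored and exactly recomputable from the samples.
#'
#' Under `stream_policy = "common"` the underlying uniform draws for
#' iteration q and pair (k,l) are identical across patients (the stream is
#' keyed by seed and iteration only), so two patients with identical partial
#' correlations produce identical chains and a zero inter-graph distance.
#'
#' @param corr A `corr_structure` from [correlation_matrix()] (or a partial
#'   correlation matrix).
#' @param n_iter Number of sampled graphs.
#' @param seed Integer seed for the uniform stream.  With
#'   `stream_policy = "common"`, pass the same seed for every patient.
#' @param stream_policy `"common"` (default) or `"independent"`; under
#'   `"independent"` the effective seed is offset by a hash of the partial
#'   correlations so streams differ across patients.
#' @param sampler `"inverse"` (default) or `"rejection"`.
#' @return An object of class `graph_chain` with fields `samples`
#'   (`n_iter x n_pairs` 0/1 matrix), `log_post`, `edge_prob` (closed-form
#'   per-pair probabilities), `pairs` (2-column index matrix), `m`,
#'   `n_iter`, `seed`, `labels`.
#' @export
sample_graph_chain <- function(corr, n_iter = 10000L, seed = 1L,
                               stream_policy = c("common", "independent"),
                               sampler = c("inverse", "rejection")) {
  stream_policy <- match.arg(stream_policy)
  sampler <- match.arg(sampler)
  r <- if (inherits(corr, "corr_structure")) corr$r else as.matrix(corr)
  m <- ncol(r)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  r_abs <- pmin(abs(r[pairs]), 1)
  p <- edge_marginal_probability(r_abs)
  np <- length(p)
  eff_seed <- as.integer(seed)
  if (stream_policy == "independent")
    eff_seed <- derive_seed(eff_seed, paste(signif(r_abs, 8), collapse = ","))
  g <- withr_seed(eff_seed, {
    if (sampler == "inverse") {
      u <- matrix(stats::runif(n_iter * np), nrow = n_iter)
      (u < matrix(p, nrow = n_iter, ncol = np, byrow = TRUE)) * 1L
    } else {
      rejection_sample_edges(p, n_iter)
    }
  })
  lp1 <- log(p); lp0 <- log1p(-p)
  log_post <- as.numeric(g %*% lp1 + (1 - g) %*% lp0)
  structure(list(samples = g, log_post = log_post, edge_prob = p,
                 pairs = unname(pairs), m = m, n_iter = as.integer(n_iter),
                 seed = eff_seed,
                 labels = if (inherits(corr, "corr_structure"))
                   corr$column_names else colnames(r)),
            class = "graph_chain")
}

# Literal accept/reject: propose each edge from the Bernoulli(0.5) prior and
# accept with probability proportional to the target two-point mass.
rejection_sample_edges <- function(p, n_iter) {
  np <- length(p)
  g <- matrix(0L, n_iter, np)
  ratio_acc <- cbind(1 - p, p) / pmax(1 - p, p)  # target/envelope, G = 0/1
  for (j in seq_len(np)) {
    need <- n_iter
    draws <- integer(0)
    while (need > 0) {
      nprop <- max(64L, ceiling(need * 2.5))
      prop <- (stats::runif(nprop) < 0.5) * 1L
      acc <- stats::runif(nprop) < ratio_acc[j, prop + 1L]
      draws <- c(draws, prop[acc])
      need <- n_iter - length(draws)
    }
    g[, j] <- draws[seq_len(n_iter)]
  }
  g
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.graph_chain <- function(x, ...) {
  cat("<graph_chain> ", x$n_iter, " graphs on ", x$m, " nodes (",
      length(x$edge_prob), " pairs), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Threshold a graph chain into a graphical model
#'
#' An edge is included iff its empirical marginal probability
#' `mhat = mean_q g_q[k,l]` reaches the cutoff probability `tau`
#' (`use = "empirical"`, the default), or iff the exact closed-form
#' probability does (`use = "closed_form"`).
#'
#' @param chain A `graph_chain`.
#' @param tau Cutoff probability in (0,1).
#' @param use `"empirical"` or `"closed_form"`.
#' @return Object of class `graphical_model` with fields `adjacency`
#'   (binary `m x m`), `edge_prob_hat` (`m x m` of empirical marginals),
#'   `tau`, `labels`.
#' @export
extract_graphical_model <- function(chain, tau = 0.6,
                                    use = c("empirical", "closed_form")) {
  use <- match.arg(use)
  if (!(tau > 0 && tau < 1)) stop("tau must lie in (0,1)")
  mhat <- colMeans(chain$samples)
  prob <- if (use == "empirical") mhat else chain$edge_prob
  m <- chain$m
  adj <- matrix(0L, m, m)
  ep <- matrix(0, m, m)
  idx <- chain$pairs
  adj[idx] <- as.integer(prob >= tau)
  ep[idx] <- mhat
  adj <- adj + t(adj)
  ep <- ep + t(ep)
  if (!is.null(chain$labels)) dimnames(adj) <- dimnames(ep) <-
      list(chain$labels, chain$labels)
  structure(list(adjacency = adj, edge_prob_hat = ep, tau = tau,
                 labels = chain$labels),
            class = "graphical_model")
}

#' @export
print.graphical_model <- function(x, ...) {
  cat("<graphical_model> ", ncol(x$adjacency), " nodes, ",
      sum(x$adjacency[upper.tri(x$adjacency)]), " edges at tau = ",
      x$tau, "\n", sep = "")
  invisible(x)
}

#' Edge list of a graphical model
#'
#' @param gm A `graphical_model`.
#' @return Data.frame with columns `from`, `to`, `probability` for the
#'   included edges, as displayed on published graph figures.
#' @export
edge_list <- function(gm) {
  idx <- which(upper.tri(gm$adjacency) & gm$adjacency == 1L, arr.ind = TRUE)
  lab <- gm$labels
  if (is.null(lab)) lab <- as.character(seq_len(ncol(gm$adjacency)))
  data.frame(from = lab[idx[, 1]], to = lab[idx[, 2]],
             probability = gm$edge_prob_hat[idx],
             stringsAsFactors = FALSE)
}
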