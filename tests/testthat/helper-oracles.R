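# Independent oracles used across the suite.  Each deliberately avoids the
# package's own code path for the quantity it checks.

# upsilon-marginalised edge density by adaptive quadrature
quad_edge_f <- function(S) {
  stats::integrate(function(v) (2 * pi * v)^(-0.5) * exp(-S^2 / (2 * v)),
                   0, 1, rel.tol = 1e-12)$value
}

# edge posterior from the quadrature density
quad_edge_prob <- function(r_abs) {
  f1 <- quad_edge_f(1 - r_abs)
  f0 <- quad_edge_f(r_abs)
  f1 / (f0 + f1)
}

# matrix-normal log density via Kronecker vectorisation:
# vec(X) ~ N(vec(M), V %x% U)
kron_mn_loglik <- function(X, M, U, V) {
  S <- kronecker(V, U)
  z <- as.numeric(X - M)
  k <- length(z)
  ch <- chol(S)
  -k / 2 * log(2 * pi) - sum(log(diag(ch))) -
    sum(backsolve(ch, z, transpose = TRUE)^2) / 2
}

# dense-grid posterior means of the score model for N_p = 2 or 3 patients,
# all constrained above 1 (side-hinted), evaluated on the exact
# unnormalised posterior (likelihood x case-based pair priors)
grid_score_means <- function(delta, lik_sd = 0.1, prior_sd = 0.1,
                             lo = 1, hi = 3, n_grid = 241) {
  g <- seq(lo, hi, length.out = n_grid)
  if (ncol(delta) == 2) {
    w <- stats::dnorm(delta[1, 2], abs(g - 1), lik_sd)
    return(sum(g * w) / sum(w))
  }
  stopifnot(ncol(delta) == 3)
  d12 <- delta[1, 2]; d13 <- delta[1, 3]; d23 <- delta[2, 3]
  W <- outer(g, g, function(s2, s3) {
    stats::dnorm(d12, abs(s2 - 1), lik_sd) *
      stats::dnorm(d13, abs(s3 - 1), lik_sd) *
      stats::dnorm(s2, case_prior_mean(s2, s3, d12, d13, d23), prior_sd) *
      stats::dnorm(s3, case_prior_mean(s3, s2, d13, d12, d23), prior_sd)
  })
  c(sum(outer(g, g, function(a, b) a) * W) / sum(W),
    sum(outer(g, g, function(a, b) b) * W) / sum(W))
}

# small deterministic patient record with a given correlation target
make_ts <- function(n, sigma, seed = 1, id = "P1", cohort = "A") {
  set.seed(seed)
  L <- chol(sigma)
  x <- matrix(stats::rnorm(n * ncol(sigma)), n) %*% L
  patient_ts(id, cohort, seq_len(n), x)
}

# tiny matrix-normal sample: X = M + U^{1/2} E V^{1/2}
rmatnorm <- function(M, U, V) {
  E <- matrix(stats::rnorm(length(M)), nrow(M))
  M + t(chol(U)) %*% E %*% chol(V)
}

# the recovery protocol used by the end-to-end experiments: cohort
# references are the clinically clearest (highest-severity) patients, all
# other patients carry a "below" severity hint, cohorts are aligned by the
# references' severity ordering
recover_scores <- function(sim, config) {
  tr <- sim$truth
  refs <- sapply(split(seq_len(nrow(tr)), tr$cohort_id),
                 function(ix) tr$patient_id[ix][which.max(tr$z[ix])])
  refz <- sapply(split(tr$z, tr$cohort_id), max)
  uni <- names(which.max(refz))
  side <- stats::setNames(rep("below", nrow(tr)), tr$patient_id)
  side <- side[!tr$patient_id %in% refs]
  res <- vod_pipeline(sim$ts, references = refs, universal_cohort = uni,
                      ref_more_severe = stats::setNames(
                        refz[setdiff(names(refs), uni)] > refz[uni],
                        setdiff(names(refs), uni)),
                      config = config, side = side)
  tab <- res$aligned$table
  list(pipeline = res,
       scores = tab$mean[match(tr$patient_id, tab$patient_id)],
       truth = tr$z)
}
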