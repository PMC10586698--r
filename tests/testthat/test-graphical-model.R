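test_that("partial correlations match closed forms", {
  # m = 2: the partial correlation equals the correlation
  for (rho in c(-0.9, -0.3, 0.2, 0.8)) {
    ts <- make_ts(2000, matrix(c(1, rho, rho, 1), 2), seed = 1)
    cs <- correlation_matrix(ts)
    expect_equal(cs$r[1, 2], cs$sigma[1, 2], tolerance = 1e-12)
  }
  # identity correlation: R is (numerically) the identity
  set.seed(2)
  x <- matrix(rnorm(5000 * 4), ncol = 4)
  cs <- correlation_matrix(x)
  expect_lt(max(abs(cs$r[upper.tri(cs$r)])), 0.05)
  expect_equal(diag(cs$r), rep(1, 4))

  # equicorrelation rho = 0.5, m = 3: all off-diagonal partials are
  # rho / (1 + rho) = 1/3 (numeric-inversion identity, checked on the
  # exact Sigma rather than an estimate)
  sig <- matrix(0.5, 3, 3); diag(sig) <- 1
  psi <- solve(sig)
  r_exact <- -psi / sqrt(tcrossprod(diag(psi)))
  expect_equal(unique(round(r_exact[upper.tri(r_exact)], 12)), 1 / 3)
  ts <- make_ts(20000, sig, seed = 3)
  cs <- correlation_matrix(ts)
  expect_equal(cs$r[1, 2], 1 / 3, tolerance = 0.03)

  # constant column is a hard error naming the column
  bad <- cbind(const = rep(1, 10), ok = rnorm(10))
  expect_error(correlation_matrix(bad), "constant column.*const")
})

test_that("closed-form edge marginal agrees with the quadrature oracle", {
  grid <- seq(0, 1, by = 0.05)
  for (S in grid) {
    expect_lt(abs(edge_marginal_f(S) - quad_edge_f(S)), 1e-8)
  }
  # frozen oracle values (normalised quadrature of the upsilon integral)
  expect_equal(edge_marginal_probability(0.5), 0.5)
  expect_equal(edge_marginal_probability(0), quad_edge_prob(0),
               tolerance = 1e-10)
  expect_equal(edge_marginal_probability(0), 0.1727613, tolerance = 1e-6)
  expect_equal(edge_marginal_probability(1), 0.8272387, tolerance = 1e-6)
  # strictly increasing in |r|
  p <- edge_marginal_probability(seq(0, 1, by = 0.01))
  expect_true(all(diff(p) > 0))
  # complement symmetry to 1e-12
  r <- seq(0, 1, by = 0.05)
  expect_lt(max(abs(edge_marginal_probability(r) +
                      edge_marginal_probability(1 - r) - 1)), 1e-12)
  expect_error(edge_marginal_probability(1.2), "\\[0, 1\\]")
})

test_that("graph chains sample the edge marginal and log the posterior", {
  r <- matrix(0.5, 2, 2); diag(r) <- 1
  ch <- sample_graph_chain(r, n_iter = 10000, seed = 21)
  expect_equal(mean(ch$samples), 0.5, tolerance = 3 * sqrt(0.25 / 10000))

  # |r| = 0: frequency matches the closed form within a 3-sigma band
  r0 <- diag(2)
  ch0 <- sample_graph_chain(r0, n_iter = 50000, seed = 22)
  p0 <- edge_marginal_probability(0)
  expect_lt(abs(mean(ch0$samples) - p0), 3 * sqrt(p0 * (1 - p0) / 50000))

  # log_post is exactly recomputable from the samples
  cs <- correlation_matrix(make_ts(400, stats::toeplitz(0.6^(0:3)), seed = 7))
  ch2 <- sample_graph_chain(cs, n_iter = 500, seed = 23)
  lp <- as.numeric(ch2$samples %*% log(ch2$edge_prob) +
                     (1 - ch2$samples) %*% log1p(-ch2$edge_prob))
  expect_identical(lp, ch2$log_post)

  # n_iter = 1 degenerate chain
  ch1 <- sample_graph_chain(cs, n_iter = 1, seed = 24)
  expect_length(ch1$log_post, 1)

  # common streams: equal partial correlations give identical chains
  chA <- sample_graph_chain(cs, 200, seed = 30, stream_policy = "common")
  chB <- sample_graph_chain(cs, 200, seed = 30, stream_policy = "common")
  expect_identical(chA$samples, chB$samples)
  chC <- sample_graph_chain(cs, 200, seed = 30, stream_policy = "independent")
  expect_false(identical(chA$samples, chC$samples))

  # the literal rejection sampler targets the same two-point law
  chR <- sample_graph_chain(r0, n_iter = 50000, seed = 25,
                            sampler = "rejection")
  expect_lt(abs(mean(chR$samples) - p0), 3 * sqrt(p0 * (1 - p0) / 50000))
})

test_that("tau thresholding is monotone and respects the cutoff", {
  cs <- correlation_matrix(make_ts(400, stats::toeplitz(0.6^(0:4)), seed = 9))
  ch <- sample_graph_chain(cs, n_iter = 2000, seed = 31)
  # all |r| = 0.5 with tau just above 0.5 gives an empty edge set
  r5 <- matrix(0.5, 3, 3); diag(r5) <- 1
  ch5 <- sample_graph_chain(r5, n_iter = 4000, seed = 32)
  gm5 <- extract_graphical_model(ch5, tau = 0.6)
  expect_equal(sum(gm5$adjacency), 0)
  # tau -> 0+ complete graph; tau -> 1- empty graph
  expect_equal(sum(extract_graphical_model(ch, 1e-6)$adjacency) / 2,
               choose(5, 2))
  expect_equal(sum(extract_graphical_model(ch, 1 - 1e-6)$adjacency), 0)
  # edge count nonincreasing in tau on a fixed chain
  taus <- seq(0.05, 0.95, by = 0.05)
  counts <- vapply(taus, function(tt)
    sum(extract_graphical_model(ch, tt)$adjacency), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # edge probabilities on the reported edge list equal the empirical means
  gm <- extract_graphical_model(ch, 0.6)
  el <- edge_list(gm)
  expect_true(all(el$probability >= 0.6))
})
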