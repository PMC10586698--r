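test_that("SQE kernel evaluates and decays as required", {
  expect_equal(sqe_kernel(0.7, 0.7, a = 2.5, ell = 0.4), 2.5)
  expect_equal(sqe_kernel(0, 1, a = 1, ell = 1), exp(-0.5))
  d <- seq(0, 3, by = 0.1)
  k <- sqe_kernel(0, d, a = 1.3, ell = 0.6)
  expect_true(all(diff(k) < 0))
  expect_error(sqe_kernel(0, 1, a = -1), "positive")
})

test_that("matrix-normal log likelihood matches its collapses and oracle", {
  set.seed(10)
  # d = 1 collapses to a multivariate Normal over the row
  # (well-separated scores keep the kernel matrix well conditioned)
  sp <- sqe_kernel_matrix(c(0.1, 0.5, 0.9, 1.4, 2.0), 1.2, 0.7, 1e-8)
  x <- matrix(rnorm(5), 1)
  mu <- matrix(0.3, 1, 5)
  s2 <- 2.1
  ll <- matrix_normal_loglik(x, mu, matrix(s2, 1, 1), sp, nugget = 0)
  or <- mvn_ll <- {
    S <- s2 * sp
    z <- as.numeric(x - mu)
    ch <- chol(S)
    -5 / 2 * log(2 * pi) - sum(log(diag(ch))) -
      sum(backsolve(ch, z, transpose = TRUE)^2) / 2
  }
  expect_equal(ll, or, tolerance = 1e-8)
  # n = 1 collapses to a multivariate Normal over the column
  U <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  xc <- matrix(rnorm(3), 3, 1)
  llc <- matrix_normal_loglik(xc, matrix(0, 3, 1), U, matrix(1, 1, 1),
                              nugget = 0)
  orc <- {
    ch <- chol(U)
    -3 / 2 * log(2 * pi) - sum(log(diag(ch))) -
      sum(backsolve(ch, as.numeric(xc), transpose = TRUE)^2) / 2
  }
  expect_equal(llc, orc, tolerance = 1e-8)
  # random instances against the Kronecker-vectorisation oracle
  for (rep in 1:5) {
    d <- sample(2:8, 1); n <- sample(2:8, 1)
    U <- crossprod(matrix(rnorm(d * d), d)) + diag(d)
    V <- crossprod(matrix(rnorm(n * n), n)) + diag(n)
    X <- matrix(rnorm(d * n), d)
    M <- matrix(rnorm(d * n), d)
    ll <- matrix_normal_loglik(X, M, U, V, nugget = 0)
    or <- kron_mn_loglik(X, M, U, V)
    expect_equal(ll, or, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant under simultaneous patient permutation", {
  set.seed(11)
  s <- c(0.05, 0.4, 0.8, 1.3, 1.7, 2.0)
  DY <- matrix(rnorm(4 * 6), 4)
  mod <- matrix_normal_model(DY, s, a = 1.5, ell = 0.5)
  ll <- matrix_normal_loglik(mod)
  p <- sample(6)
  modp <- matrix_normal_model(DY[, p], s[p], a = 1.5, ell = 0.5)
  expect_equal(matrix_normal_loglik(modp), ll, tolerance = 1e-10)
})

test_that("vanishing amplitude stays finite via the nugget", {
  set.seed(12)
  mod <- matrix_normal_model(matrix(rnorm(12), 3), runif(4), a = 1e-12,
                             ell = 0.5, nugget = 1e-8)
  ll <- matrix_normal_loglik(mod)
  expect_true(is.finite(ll))
})

test_that("degenerate Sigma_Y escalates the nugget and then errors", {
  set.seed(13)
  # duplicated variable: singular empirical covariance stays usable
  DY <- matrix(rnorm(3 * 6), 3)
  DY <- rbind(DY, DY[3, ])
  mod <- matrix_normal_model(DY, runif(6), 1, 0.5, nugget = 1e-8)
  ll <- suppressWarnings(matrix_normal_loglik(mod))
  expect_true(is.finite(ll))
  # a slightly indefinite matrix triggers the escalation path with warning
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  A <- q %*% diag(c(1, 0.5, -1e-7)) %*% t(q)
  A <- (A + t(A)) / 2
  expect_warning(
    llA <- matrix_normal_loglik(matrix(0, 3, 2), matrix(0, 3, 2), A,
                                diag(2), nugget = 1e-8),
    "nugget escalation")
  expect_true(is.finite(llA))
  # an outright broken "covariance" must fail loudly with a condition report
  bad <- diag(c(1, -5, 1))
  expect_error(suppressWarnings(
    matrix_normal_loglik(matrix(0, 3, 2), matrix(0, 3, 2), bad, diag(2))),
    "condition number")
})

test_that("hyperparameter fitting needs enough patients", {
  expect_error(fit_hyperparameters(c(0, 1), matrix(rnorm(8), 4, 2)),
               "at least 3")
})

test_that("uninformative data leave the test-score posterior y-invariant", {
  # all training columns identical: y_test carries no discriminating
  # information, so independent chains must agree on the s_test marginal,
  # which must spread over most of the prior range.  (The posterior is
  # not exactly the prior: the matrix-normal determinant depends on where
  # s_test sits relative to the training scores even for degenerate data,
  # a property of the model itself.)
  set.seed(99)
  DY <- matrix(rep(rnorm(5), 8), 5, 8)
  cfg <- run_config(gp = list(n_iter = 12000L, burn_in = 2000L,
                              s_proposal_sd = 0.6), seed = 2)
  s_tr <- seq(-1, 1, length.out = 8)
  pr <- list(type = "uniform", range = c(-2, 2))
  r1 <- learn_test_score(DY, s_tr, DY[, 1], prior = pr, config = cfg,
                         seed = 11)
  r2 <- learn_test_score(DY, s_tr, DY[, 1], prior = pr, config = cfg,
                         seed = 12)
  ks <- suppressWarnings(stats::ks.test(r1$draws[, "s_test"],
                                        r2$draws[, "s_test"]))
  expect_lt(unname(ks$statistic), 0.05)
  # broad spread over the prior support (no spurious concentration)
  expect_lt(r1$hpd["s_test", 1], -1.4)
  expect_gt(r1$hpd["s_test", 2], 1.4)
  expect_error(learn_test_score(DY, s_tr, DY[, 1],
                                prior = list(type = "uniform",
                                             range = c(2, -2)),
                                config = cfg),
               "empty prior interval")
})

test_that("a test vector copied from a training patient lands on its score", {
  # strong score-attribute link, low noise: nearest-neighbour consistency
  set.seed(21)
  n <- 12; d <- 6
  s <- seq(0, 2, length.out = n)
  B <- matrix(runif(d, 0.8, 1.2), d)
  DY <- B %*% t(s) + matrix(rnorm(d * n, 0, 0.05), d)
  cfg <- run_config(gp = list(n_iter = 8000L, burn_in = 2000L), seed = 3)
  j <- 7
  res <- learn_test_score(DY, s, DY[, j],
                          prior = list(type = "uniform", range = c(-1, 3)),
                          config = cfg)
  expect_lt(abs(res$mean["s_test"] - s[j]), 0.1)
  expect_true(res$hpd["s_test", 1] <= res$mean["s_test"] &&
                res$mean["s_test"] <= res$hpd["s_test", 2])
})
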