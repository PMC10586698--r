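#' Squared-exponential kernel
#'
#' `K(s_i, s_j) = a * exp(-(s_i - s_j)^2 / (2 * ell^2))`: the covariance
#' between two patients' pre-transplant vectors declines with the squared
#' difference of their scores; `a` is the amplitude, `ell` the length
#' scale (both > 0, in score units).
#'
#' @param s_i,s_j Numeric vectors of scores (recycled against each other).
#' @param a Amplitude, > 0.
#' @param ell Length scale, > 0.
#' @return Kernel values, vectorised.
#' @export
sqe_kernel <- function(s_i, s_j, a = 1, ell = 1) {
  if (a <= 0 || ell <= 0) stop("kernel hyperparameters must be positive")
  a * exp(-(s_i - s_j)^2 / (2 * ell^2))
}

# Kernel matrix over a score vector, with nugget jitter on the diagonal.
sqe_kernel_matrix <- function(s, a, ell, nugget = 1e-8) {
  K <- a * exp(-outer(s, s, "-")^2 / (2 * ell^2))
  K + nugget * diag(length(s))
}

#' Regularised empirical covariance of the variables
#'
#' Unbiased empirical covariance across patients, shrunk toward its own
#' diagonal: `(1 - shrink) * S + shrink * diag(S)`, with a small floor on
#' the diagonal target so constant variables stay invertible.  With more
#' variables than patients (`d >= N_p`, as in a 30-attribute, 25-patient
#' cohort) the raw estimate is singular and plugging its pseudo-inverse
#' into the matrix-normal likelihood degenerates (directions outside the
#' sample span get arbitrary weight); diagonal-target shrinkage is the
#' standard repair and is applied wherever a covariance is built from
#' patient columns.
#'
#' @param x Matrix with variables in rows, patients in columns.
#' @param shrink Shrinkage weight in `[0, 1)`, default 0.1.
#' @return A `d x d` symmetric positive-semidefinite matrix.
#' @export
shrunk_covariance <- function(x, shrink = 0.1) {
  S <- stats::cov(t(x))
  dg <- diag(S)
  floor_v <- 1e-4 * mean(dg[dg > 0])
  if (!is.finite(floor_v) || floor_v <= 0) floor_v <- 1e-8
  (1 - shrink) * S + shrink * diag(pmax(dg, floor_v), nrow(S))
}

# Cholesky with escalating nugget (x10 per step, capped); hard error with a
# condition-number report past the cap.  The nugget is relative to the mean
# diagonal, so unstandardised attribute scales do not defeat it.
chol_nugget <- function(A, nugget = 1e-8, cap = 1e-4, label = "covariance") {
  n <- ncol(A)
  scale <- mean(diag(A))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  nug <- nugget
  repeat {
    ch <- tryCatch(chol(A + nug * scale * diag(n)), error = function(e) NULL)
    if (!is.null(ch)) {
      if (nug > nugget)
        warning(label, " needed nugget escalation to ", format(nug),
                call. = FALSE)
      return(list(chol = ch, nugget = nug * scale))
    }
    if (nug >= cap) {
      ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
      stop(label, " not positive definite at nugget cap ", format(cap),
           "; condition number ", format(max(ev) / max(min(ev), 1e-300)))
    }
    nug <- nug * 10
  }
}

#' Matrix-normal model of the pre-transplant data
#'
#' Stacks the encoded pre-transplant vectors as a `d x N_p` matrix `D_Y`
#' (columns = patients), sets the mean matrix `mu` to the across-patient
#' mean of each variable (constant rows), fixes the inter-variable
#' covariance `Sigma_Y` at the unbiased empirical covariance of the
#' variables, and parametrises the inter-patient covariance
#' `Sigma_Patient` by the [sqe_kernel()] of the learnt scores.
#'
#' @param table A `pretransplant_table` (or a `d x N_p` numeric matrix).
#' @param scores Numeric vector of `N_p` learnt scores (design inputs).
#' @param a,ell Kernel hyperparameters.
#' @param nugget Base jitter added to both covariance diagonals.
#' @param shrink Diagonal-target shrinkage for the empirical `Sigma_Y`
#'   (see [shrunk_covariance()]).
#' @return Object of class `matrix_normal_model` with fields `D_Y`, `mu`,
#'   `Sigma_Y`, `Sigma_Patient`, `scores`, `a`, `ell`, `nugget`.
#' @export
matrix_normal_model <- function(table, scores, a = 1, ell = 1,
                                nugget = 1e-8, shrink = 0.1) {
  DY <- if (inherits(table, "pretransplant_table")) table$encoded
        else as.matrix(table)
  n <- ncol(DY)
  if (length(scores) != n)
    stop("need one score per patient column: ", length(scores), " vs ", n)
  mu <- matrix(rowMeans(DY), nrow(DY), n)
  Sigma_Y <- shrunk_covariance(DY, shrink)      # d x d
  Sigma_P <- sqe_kernel_matrix(scores, a, ell, nugget)
  structure(list(D_Y = DY, mu = mu, Sigma_Y = Sigma_Y,
                 Sigma_Patient = Sigma_P, scores = scores,
                 a = a, ell = ell, nugget = nugget),
            class = "matrix_normal_model")
}

#' Matrix-normal log density
#'
#' Log density of a `d x n` matrix `X` under the matrix-normal law with
#' mean `M`, among-row covariance `U` (`d x d`) and among-column covariance
#' `V` (`n x n`):
#' `-(d n / 2) log 2 pi - (n/2) log|U| - (d/2) log|V|
#'  - tr(V^-1 (X - M)^T U^-1 (X - M)) / 2`,
#' computed through Cholesky factors with an escalating nugget.  This is
#' the standard normalisation for the separable (Kronecker) covariance
#' `V %x% U` of `vec(X)`.
#'
#' @param x A `matrix_normal_model`, or a numeric matrix (then `mean`,
#'   `row_cov`, `col_cov` are required).
#' @param mean,row_cov,col_cov Mean matrix and the two covariances when `x`
#'   is a plain matrix.
#' @param nugget Base jitter.
#' @return The log density (a single number).
#' @export
matrix_normal_loglik <- function(x, mean = NULL, row_cov = NULL,
                                 col_cov = NULL, nugget = 1e-8) {
  if (inherits(x, "matrix_normal_model")) {
    mean <- x$mu; row_cov <- x$Sigma_Y; col_cov <- x$Sigma_Patient
    nugget <- x$nugget
    x <- x$D_Y
  }
  X <- as.matrix(x)
  d <- nrow(X); n <- ncol(X)
  Z <- X - mean
  cu <- chol_nugget(row_cov, nugget, label = "row covariance")
  cv <- chol_nugget(col_cov, nugget, label = "column covariance")
  # tr(V^-1 Z^T U^-1 Z) = || L_u^-T Z L_v^-1 ||_F^2 via triangular solves
  W <- backsolve(cu$chol, Z, transpose = TRUE)
  W <- t(backsolve(cv$chol, t(W), transpose = TRUE))
  logdet_u <- 2 * sum(log(diag(cu$chol)))
  logdet_v <- 2 * sum(log(diag(cv$chol)))
  -(d * n / 2) * log(2 * pi) - (n / 2) * logdet_u - (d / 2) * logdet_v -
    sum(W * W) / 2
}

# Shared MH engine: component-wise Gaussian random walk with adaptive
# proposal scaling during burn-in only.  `indep` optionally describes an
# independence-proposal mixture for one component (used for the test score,
# whose posterior can be a set of narrow spikes at the training scores that
# a pure random walk cannot hop between): a list with `j` (component
# index), `rdraw()` (sampler from the proposal), `ldens(x)` (its log
# density) and `prob` (mixture weight).
gp_mh <- function(init, log_post, n_iter, burn_in, prop_sd, seed,
                  adapt_target = 0.3, indep = NULL) {
  k <- length(init)
  cur <- init
  lp_cur <- log_post(cur)
  if (!is.finite(lp_cur)) stop("log posterior not finite at initial state")
  draws <- matrix(NA_real_, n_iter - burn_in, k,
                  dimnames = list(NULL, names(init)))
  acc <- numeric(k); acc_win <- numeric(k); win <- 0L
  withr_seed(seed, {
    for (t in seq_len(n_iter)) {
      for (j in seq_len(k)) {
        use_indep <- !is.null(indep) && j == indep$j &&
          stats::runif(1) < indep$prob
        prop <- cur
        if (use_indep) {
          prop[j] <- indep$rdraw()
          lhast <- indep$ldens(cur[j]) - indep$ldens(prop[j])
        } else {
          prop[j] <- cur[j] + stats::rnorm(1, 0, prop_sd[j])
          lhast <- 0
        }
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) &&
            log(stats::runif(1)) < lp_prop - lp_cur + lhast) {
          cur <- prop; lp_cur <- lp_prop
          acc[j] <- acc[j] + 1; acc_win[j] <- acc_win[j] + 1
        }
      }
      win <- win + 1L
      if (t <= burn_in && win == 100L) {   # adapt only during burn-in
        rate <- acc_win / 100
        prop_sd <- prop_sd * exp(rate - adapt_target)
        acc_win[] <- 0; win <- 0L
      }
      if (t > burn_in) draws[t - burn_in, ] <- cur
    }
  })
  list(draws = draws, acceptance = acc / n_iter, prop_sd = prop_sd)
}

#' Learn the kernel hyperparameters on the training cohort
#'
#' Random-walk Metropolis on `(log a, log ell)` under the matrix-normal
#' likelihood of the training table (with `Sigma_Y` fixed at the unbiased
#' empirical covariance and `mu` at the across-patient means) and wide
#' log-Normal priors on `a` and `ell`.
#'
#' @param scores Learnt scores of the `N_p` training patients.
#' @param table `pretransplant_table` or `d x N_p` matrix.
#' @param config A [run_config()] (uses `config$gp`).
#' @param seed Integer seed (defaults to a child of `config$seed`).
#' @param init Optional named start `c(log_a = , log_ell = )`.
#' @return Object of class `gp_fit`: `draws` (columns `a`, `ell`), `mean`,
#'   `hpd`, `acceptance`, plus the fixed `Sigma_Y`, `mu`, `scores`.
#' @export
fit_hyperparameters <- function(scores, table, config = run_config(),
                                seed = NULL, init = NULL, shrink = 0.1) {
  DY <- if (inherits(table, "pretransplant_table")) table$encoded
        else as.matrix(table)
  n <- ncol(DY); d <- nrow(DY)
  if (n < 3) stop("need at least 3 patients to fit hyperparameters")
  if (length(scores) != n) stop("one score per patient required")
  g <- config$gp
  if (is.null(seed)) seed <- derive_seed(config$seed, "gp-fit")
  mu <- rowMeans(DY)
  Z <- DY - mu
  Sigma_Y <- shrunk_covariance(DY, shrink)
  cu <- suppressWarnings(chol_nugget(Sigma_Y, 1e-8, label = "Sigma_Y"))
  logdet_u <- 2 * sum(log(diag(cu$chol)))
  W <- backsolve(cu$chol, Z, transpose = TRUE)
  Q <- crossprod(W)                      # Z^T Sigma_Y^-1 Z, n x n
  log_post <- function(th) {
    a <- exp(th[1]); ell <- exp(th[2])
    Sp <- sqe_kernel_matrix(scores, a, ell, 0)
    # smooth kernels are numerically rank-deficient at moderate ell; the
    # escalating jitter keeps the whole (a, ell) range reachable
    cv <- tryCatch(suppressWarnings(chol_nugget(Sp, 1e-8)$chol),
                   error = function(e) NULL)
    if (is.null(cv)) return(-Inf)
    logdet_v <- 2 * sum(log(diag(cv)))
    Spi_Q <- chol2inv(cv) * Q
    ll <- -(d * n / 2) * log(2 * pi) - (n / 2) * logdet_u -
      (d / 2) * logdet_v - sum(Spi_Q) / 2
    ll + stats::dnorm(th[1], 0, g$log_a_prior_sd, log = TRUE) +
      stats::dnorm(th[2], 0, g$log_ell_prior_sd, log = TRUE)
  }
  if (is.null(init)) init <- c(log_a = 0, log_ell = 0)
  fit <- gp_mh(init, log_post, g$n_iter, g$burn_in,
               prop_sd = rep(g$proposal_sd, 2), seed = seed)
  draws <- exp(fit$draws)
  colnames(draws) <- c("a", "ell")
  hpd <- t(apply(draws, 2, hpd_interval))
  colnames(hpd) <- c("lower", "upper")
  structure(list(draws = draws, mean = colMeans(draws), hpd = hpd,
                 acceptance = fit$acceptance, Sigma_Y = Sigma_Y,
                 mu = mu, scores = scores),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("<gp_fit> posterior means a = ", signif(x$mean["a"], 4),
      ", ell = ", signif(x$mean["ell"], 4), " (",
      nrow(x$draws), " retained draws)\n", sep = "")
  invisible(x)
}

#' Learn a prospective patient's score jointly with the hyperparameters
#'
#' Appends the encoded test vector `y_test` as an extra column of the data
#' (the augmented matrix `D_aug`), recomputes the mean matrix and the
#' inter-variable covariance `Psi_Y` on the augmented data, and runs joint
#' MCMC over `(log a, log ell, s_test)`, rebuilding the
#' `(N_p + 1) x (N_p + 1)` kernel matrix from the current state at every
#' iteration.  The elicited prior on `s_test` is Uniform over
#' `config$gp$s_test_range` by default; extrapolation outside the convex
#' hull of the training attributes (e.g. a condition no training patient
#' had) uses a clinician-elicited Normal prior instead.
#'
#' @param table Training `pretransplant_table` or `d x N_p` matrix.
#' @param scores Learnt training scores.
#' @param y_test Encoded test vector of length `d` (use
#'   [encode_new_patient()] so the training dummy coding is applied).
#' @param prior List: `list(type = "uniform", range = c(lo, hi))` or
#'   `list(type = "normal", mean = , sd = )`.
#' @param config A [run_config()].
#' @param seed Integer seed.
#' @param freeze_psi_y If `TRUE`, keep the training `Sigma_Y` instead of
#'   recomputing `Psi_Y` on the augmented data (ablation switch).
#' @param init_s Optional starting value for `s_test` (default: prior
#'   mean / range midpoint).
#' @return Object of class `test_score_result`: `draws` (columns `a`,
#'   `ell`, `s_test`), `mean`, `hpd`, `status` (via [classify_status()] on
#'   the `s_test` posterior), `acceptance`.
#' @export
learn_test_score <- function(table, scores, y_test,
                             prior = list(type = "uniform"),
                             config = run_config(), seed = NULL,
                             freeze_psi_y = FALSE, init_s = NULL,
                             shrink = 0.1) {
  DY <- if (inherits(table, "pretransplant_table")) table$encoded
        else as.matrix(table)
  n <- ncol(DY); d <- nrow(DY)
  if (length(y_test) != d) stop("y_test must have length d = ", d)
  g <- config$gp
  if (is.null(seed)) seed <- derive_seed(config$seed, "gp-test")
  if (is.null(prior$type)) prior$type <- "uniform"
  if (prior$type == "uniform" && is.null(prior$range))
    prior$range <- g$s_test_range
  if (prior$type == "uniform" && prior$range[1] >= prior$range[2])
    stop("empty prior interval for s_test")

  D_aug <- cbind(DY, y_test)
  mu_aug <- rowMeans(D_aug)
  Z <- D_aug - mu_aug
  Psi_Y <- if (freeze_psi_y) shrunk_covariance(DY, shrink)
           else shrunk_covariance(D_aug, shrink)
  cu <- suppressWarnings(chol_nugget(Psi_Y, 1e-8, label = "Psi_Y"))
  logdet_u <- 2 * sum(log(diag(cu$chol)))
  W <- backsolve(cu$chol, Z, transpose = TRUE)
  A <- crossprod(W)                      # (n+1) x (n+1), fixed over MCMC
  na <- n + 1
  log_prior_s <- function(s) {
    if (prior$type == "uniform") {
      if (s < prior$range[1] || s > prior$range[2]) -Inf else 0
    } else {
      stats::dnorm(s, prior$mean, prior$sd, log = TRUE)
    }
  }
  log_post <- function(th) {
    lps <- log_prior_s(th[3])
    if (!is.finite(lps)) return(-Inf)
    a <- exp(th[1]); ell <- exp(th[2])
    Sp <- sqe_kernel_matrix(c(scores, th[3]), a, ell, 0)
    cv <- tryCatch(suppressWarnings(chol_nugget(Sp, 1e-8)$chol),
                   error = function(e) NULL)
    if (is.null(cv)) return(-Inf)
    logdet_v <- 2 * sum(log(diag(cv)))
    ll <- -(d * na / 2) * log(2 * pi) - (na / 2) * logdet_u -
      (d / 2) * logdet_v - sum(chol2inv(cv) * A) / 2
    ll + stats::dnorm(th[1], 0, g$log_a_prior_sd, log = TRUE) +
      stats::dnorm(th[2], 0, g$log_ell_prior_sd, log = TRUE) + lps
  }
  if (is.null(init_s))
    init_s <- if (prior$type == "uniform") mean(prior$range) else prior$mean
  init <- c(log_a = 0, log_ell = 0, s_test = init_s)
  indep <- list(j = 3L, prob = 0.25,
                rdraw = if (prior$type == "uniform")
                  function() stats::runif(1, prior$range[1], prior$range[2])
                else function() stats::rnorm(1, prior$mean, prior$sd),
                ldens = log_prior_s)
  fit <- gp_mh(init, log_post, g$n_iter, g$burn_in,
               prop_sd = c(g$proposal_sd, g$proposal_sd, g$s_proposal_sd),
               seed = seed, indep = indep)
  draws <- cbind(a = exp(fit$draws[, 1]), ell = exp(fit$draws[, 2]),
                 s_test = fit$draws[, 3])
  hpd <- t(apply(draws, 2, hpd_interval))
  colnames(hpd) <- c("lower", "upper")
  means <- colMeans(draws)
  status <- classify_status(means["s_test"], hpd["s_test", "upper"],
                            thresholds = config$status_thresholds)
  structure(list(draws = draws, mean = means, hpd = hpd,
                 status = unname(status), acceptance = fit$acceptance),
            class = "test_score_result")
}

#' @export
print.test_score_result <- function(x, ...) {
  cat("<test_score_result> mean score ", signif(x$mean["s_test"], 4),
      ", 95% HPD [", signif(x$hpd["s_test", 1], 4), ", ",
      signif(x$hpd["s_test", 2], 4), "], predicted status ", x$status,
      "\n", sep = "")
  invisible(x)
}
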