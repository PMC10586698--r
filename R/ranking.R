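#' Leave-one-variable-out likelihood drop
#'
#' `gamma_n` is the matrix-normal log likelihood of the data with variable
#' `n` removed (row `n` deleted from the data and mean matrices, row and
#' column `n` deleted from the empirical inter-variable covariance) minus
#' the log likelihood of the full data, both evaluated at the same kernel
#' hyperparameters — `Sigma_Patient` depends only on the scores and
#' `(a, ell)` and is unchanged by the removal.  The more negative
#' `gamma_n`, the more sorely the variable is missed by the model; a
#' positive `gamma_n` means the model improves without it.
#'
#' @param n Variable index (or name) to remove.
#' @param table `pretransplant_table` or `d x N_p` matrix.
#' @param scores Learnt patient scores.
#' @param a,ell Kernel hyperparameters (posterior means from
#'   [fit_hyperparameters()] by default usage).
#' @param nugget Base jitter for the covariance solves.
#' @return The likelihood difference (a single number).
#' @export
gamma_statistic <- function(n, table, scores, a, ell, nugget = 1e-8) {
  DY <- if (inherits(table, "pretransplant_table")) table$encoded
        else as.matrix(table)
  d <- nrow(DY)
  if (d < 2) stop("need at least 2 variables to remove one")
  if (is.character(n)) n <- match(n, rownames(DY))
  if (is.na(n) || n < 1 || n > d) stop("invalid variable index")
  full <- matrix_normal_model(DY, scores, a, ell, nugget)
  red <- full
  red$D_Y <- DY[-n, , drop = FALSE]
  red$mu <- full$mu[-n, , drop = FALSE]
  red$Sigma_Y <- full$Sigma_Y[-n, -n, drop = FALSE]
  matrix_normal_loglik(red) - matrix_normal_loglik(full)
}

#' Rank pre-transplant variables by influence on the score
#'
#' Computes [gamma_statistic()] for every variable and sorts ascending
#' (most negative = most influential = rank 1); ties are broken by variable
#' name, deterministically.  `mode = "refit"` additionally re-learns
#' `(a, ell)` on each reduced data set and reports the difference of their
#' posterior means, the difference of maximum log-posterior values, and the
#' row-wise sum of all difference columns.
#'
#' @inheritParams gamma_statistic
#' @param mode `"fixed"` (default: hyperparameters held at the supplied
#'   values) or `"refit"`.
#' @param config A [run_config()] (used by `"refit"` only).
#' @param seed Seed for the refits.
#' @return Data.frame of class `ranking_table`: columns `attribute`,
#'   `gamma`, `positive` (flag: likelihood improves on removal), `rank`;
#'   refit mode adds `diff_ell`, `diff_a`, `diff_posterior`,
#'   `sum_of_differences`.
#' @export
rank_variables <- function(table, scores, a, ell,
                           mode = c("fixed", "refit"),
                           config = run_config(), seed = NULL,
                           nugget = 1e-8) {
  mode <- match.arg(mode)
  DY <- if (inherits(table, "pretransplant_table")) table$encoded
        else as.matrix(table)
  d <- nrow(DY)
  nms <- rownames(DY)
  if (is.null(nms)) nms <- paste0("Y", seq_len(d))
  gam <- vapply(seq_len(d), gamma_statistic, numeric(1),
                table = DY, scores = scores, a = a, ell = ell,
                nugget = nugget)
  out <- data.frame(attribute = nms, gamma = gam,
                    positive = gam > 0, stringsAsFactors = FALSE)
  if (mode == "refit") {
    if (is.null(seed)) seed <- derive_seed(config$seed, "rank-refit")
    full_fit <- fit_hyperparameters(scores, DY, config,
                                    seed = derive_seed(seed, "full"))
    full_max <- max_log_posterior(full_fit, DY, scores, config)
    diff_ell <- diff_a <- diff_post <- numeric(d)
    for (nn in seq_len(d)) {
      fit_n <- fit_hyperparameters(scores, DY[-nn, , drop = FALSE], config,
                                   seed = derive_seed(seed, paste0("v", nn)))
      diff_ell[nn] <- fit_n$mean["ell"] - full_fit$mean["ell"]
      diff_a[nn] <- fit_n$mean["a"] - full_fit$mean["a"]
      diff_post[nn] <- max_log_posterior(fit_n, DY[-nn, , drop = FALSE],
                                         scores, config) - full_max
    }
    out$diff_ell <- diff_ell
    out$diff_a <- diff_a
    out$diff_posterior <- diff_post
    out$sum_of_differences <- out$gamma + diff_ell + diff_a + diff_post
  }
  out <- out[order(out$gamma, out$attribute), , drop = FALSE]
  out$rank <- seq_len(d)
  rownames(out) <- NULL
  class(out) <- c("ranking_table", "data.frame")
  out
}

# Maximum (over retained draws) of the log posterior of a gp_fit; the
# "difference in posterior" refit column is the difference of these maxima,
# documented as an interpretation.
max_log_posterior <- function(fit, DY, scores, config) {
  g <- config$gp
  mu <- rowMeans(DY)
  Sigma_Y <- shrunk_covariance(DY)
  lp <- function(a, ell) {
    mod <- structure(list(D_Y = DY, mu = matrix(mu, nrow(DY), ncol(DY)),
                          Sigma_Y = Sigma_Y,
                          Sigma_Patient = sqe_kernel_matrix(scores, a, ell),
                          nugget = 1e-8),
                     class = "matrix_normal_model")
    matrix_normal_loglik(mod) +
      stats::dnorm(log(a), 0, g$log_a_prior_sd, log = TRUE) +
      stats::dnorm(log(ell), 0, g$log_ell_prior_sd, log = TRUE)
  }
  idx <- unique(round(seq(1, nrow(fit$draws), length.out = 200)))
  max(vapply(idx, function(i) lp(fit$draws[i, "a"], fit$draws[i, "ell"]),
             numeric(1)))
}
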