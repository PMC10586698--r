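test_that("case-based prior means follow the |s - 1| algebra", {
  # same side below 1, reference-distance ordering flips the sign
  expect_equal(case_prior_mean(0.8, 0.6, 0.2, 0.4, 0.2), 0.6 + 0.2)
  expect_equal(case_prior_mean(0.6, 0.8, 0.4, 0.2, 0.2), 0.8 - 0.2)
  # same side at/above 1
  expect_equal(case_prior_mean(1.5, 1.2, 0.5, 0.2, 0.3), 1.2 + 0.3)
  expect_equal(case_prior_mean(1.2, 1.5, 0.2, 0.5, 0.3), 1.5 - 0.3)
  # coincident patients: zero pair distance returns the comparator
  expect_equal(case_prior_mean(1.3, 1.3, 0.3, 0.3, 0), 1.3)
  expect_equal(case_prior_mean(0.7, 0.7, 0.3, 0.3, 0), 0.7)
  # mixed sides, derived from delta_1j = |s_j - 1| and
  # delta_ij = |delta_1j - delta_1i|:
  # s_j >= 1 > s_i with delta_1j > delta_1i: s_j = 2 - s_i + delta_ij
  expect_equal(case_prior_mean(1.6, 0.8, 0.6, 0.2, 0.4), 2 - 0.8 + 0.4)
  expect_equal(case_prior_mean(1.1, 0.6, 0.1, 0.4, 0.3), 2 - 0.6 - 0.3)
  # s_j < 1 <= s_i mirrored
  expect_equal(case_prior_mean(0.4, 1.2, 0.6, 0.2, 0.4), 2 - 1.2 - 0.4)
  expect_equal(case_prior_mean(0.9, 1.4, 0.1, 0.4, 0.3), 2 - 1.4 + 0.3)
  # vectorised over comparators
  out <- case_prior_mean(1.5, c(1.2, 0.8), 0.5, c(0.2, 0.2), c(0.3, 0.4))
  expect_equal(out, c(1.5, 1.6))
  expect_error(case_prior_mean(1, 1, -0.1, 0, 0), ">= 0")
})

test_that("self-consistency of the mixed-case algebra on exact geometry", {
  # place true scores on a line, derive the exact distances, and check
  # every case returns the true s_j
  s <- c(1, 1.4, 0.7, 1.9, 0.3)   # patient 1 = reference
  d1 <- abs(s - 1)
  for (j in 2:5) for (i in setdiff(2:5, j)) {
    dij <- abs(d1[j] - d1[i])
    expect_equal(case_prior_mean(s[j], s[i], d1[j], d1[i], dij), s[j],
                 info = paste(j, i))
  }
})

test_that("HPD intervals are shortest and contain the mass", {
  set.seed(1)
  x <- c(rnorm(5000), rnorm(200, 8))   # outlier lobe must be excluded
  h <- hpd_interval(x, 0.95)
  expect_lt(h[2], 5)
  expect_gte(mean(x >= h[1] & x <= h[2]), 0.95 - 1e-3)
  # against the known Normal quantile width
  y <- rnorm(20000)
  hy <- hpd_interval(y)
  expect_equal(hy[2] - hy[1], 2 * qnorm(0.975), tolerance = 0.06)
})

test_that("MCMC score means agree with the dense-grid oracle", {
  cfg <- run_config(mcmc = list(n_sweeps = 6000L, burn_in = 2000L), seed = 5)
  # N_p = 2, zero distance: both branches coincide at 1
  d0 <- matrix(0, 2, 2)
  po0 <- learn_scores(d0, 1, cfg)
  expect_lt(abs(po0$mean[2] - 1), 0.05)
  # N_p = 2, delta = 0.5, anchored above 1
  d <- matrix(c(0, 0.5, 0.5, 0), 2)
  po <- learn_scores(d, 1, cfg, side = c(NA, "above"))
  oracle <- grid_score_means(d)
  expect_lt(abs(po$mean[2] - oracle), 0.05)
  expect_lt(abs(po$mean[2] - 1.5), 0.05)
  expect_true(po$hpd[2, 1] <= po$mean[2] && po$mean[2] <= po$hpd[2, 2])
  # N_p = 3, consistent collinear configuration above 1
  d3 <- matrix(0, 3, 3)
  d3[1, 2] <- d3[2, 1] <- 0.2
  d3[1, 3] <- d3[3, 1] <- 0.5
  d3[2, 3] <- d3[3, 2] <- 0.3
  po3 <- learn_scores(d3, 1, cfg, side = c(NA, "above", "above"))
  or3 <- grid_score_means(d3)
  expect_lt(max(abs(po3$mean[2:3] - or3)), 0.05)
  expect_lt(max(abs(po3$mean[2:3] - c(1.2, 1.5))), 0.05)
  # reference is pinned at 1 and its HPD is NA
  expect_equal(unname(po3$mean[1]), 1)
  expect_true(all(is.na(po3$hpd[1, ])))
})

test_that("posterior |s - 1| tracks the observed reference distance", {
  cfg <- run_config(mcmc = list(n_sweeps = 4000L, burn_in = 1000L), seed = 7)
  set.seed(31)
  s_true <- c(1, 1 + runif(4, 0.2, 0.9))
  delta <- abs(outer(s_true, s_true, "-"))
  po <- learn_scores(delta, 1, cfg, side = c(NA, rep("above", 4)))
  for (j in 2:5) {
    dev <- abs(mean(abs(po$draws[, j] - 1)) - delta[1, j])
    se <- 3 * stats::sd(abs(po$draws[, j] - 1)) / sqrt(50)  # generous ESS
    expect_lt(dev, max(se, 0.05))
  }
})

test_that("cohort alignment reproduces the reference worked example", {
  # three cohorts, universal reference clinically more severe than the
  # other two cohort references; printed inter-reference distances
  po_I <- reference_only_posterior("I-ref")
  po_II <- reference_only_posterior("II-ref")
  po_III <- reference_only_posterior("III-ref")
  al <- align_cohorts(
    list(I = po_I, II = po_II, III = po_III), universal_cohort = "II",
    alignments = data.frame(cohort_id = c("I", "III"), d = c(1.17, 2.43),
                            more_severe = FALSE))
  tab <- al$table
  expect_equal(tab$mean[tab$patient_id == "I-ref"], 1 - 1.17)
  expect_equal(tab$mean[tab$patient_id == "III-ref"], 1 - 2.43)
  expect_equal(unname(al$shifts["III"]), -2.43)
  expect_equal(unname(al$shifts["II"]), 0)
  # shifted references carry no uncertainty
  expect_true(all(is.na(tab$hpd_lower[tab$is_reference])))
  # d = 0 is the identity transformation
  al0 <- align_cohorts(list(A = po_I, B = po_II), "A",
                       data.frame(cohort_id = "B", d = 0, more_severe = TRUE))
  expect_equal(al0$table$mean, c(1, 1))
  # missing severity ordering is a hard error
  expect_error(align_cohorts(list(A = po_I, B = po_II), "A",
                             data.frame(cohort_id = "B", d = 1,
                                        more_severe = NA)),
               "severity ordering")
})

test_that("alignment commutes with a constant shift (equivariance)", {
  set.seed(4)
  mk <- function(offset) {
    draws <- matrix(rnorm(200, 1.2, 0.1) + offset, 100, 2)
    colnames(draws) <- c("r", "p")
    structure(list(draws = draws, mean = colMeans(draws) - c(offset, 0),
                   hpd = rbind(c(NA, NA), hpd_interval(draws[, 2])),
                   reference = 1L, patient_ids = c("r", "p"),
                   acceptance = c(r = 0, p = 0.4)),
              class = "score_posterior")
  }
  base <- mk(0)
  al1 <- align_cohorts(list(U = reference_only_posterior("u"), B = base), "U",
                       data.frame(cohort_id = "B", d = 0.7,
                                  more_severe = TRUE))
  al2 <- align_cohorts(list(U = reference_only_posterior("u"), B = base), "U",
                       data.frame(cohort_id = "B", d = 0.7 + 0.3,
                                  more_severe = TRUE))
  expect_equal(al2$table$mean[-1], al1$table$mean[-1] + 0.3)
})

test_that("status classification applies the published cutoffs", {
  expect_equal(classify_status(0.11), "N")          # boundary is negative
  expect_equal(classify_status(0.44), "Y")
  expect_equal(classify_status(-2.32), "N")
  expect_equal(classify_status(c(0.1101, 0.109)), c("Y", "N"))
  # uncertainty-aware mode uses the upper HPD bound against 0.31
  expect_equal(classify_status(0.11, upper_hpd = 0.31, mode = "uncertainty"),
               "N")
  expect_equal(classify_status(0.2, upper_hpd = 0.35, mode = "uncertainty"),
               "Y")
})
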