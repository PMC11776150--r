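test_that("pooled t statistics match the textbook formula", {
  m <- log_em(matrix(c(1, 4, 2, 5, 3, 6), 1, 6))  # one gene, A then B interleaved
  tv <- two_population_t(m, groupA = c(1, 3, 5), groupB = c(2, 4, 6))
  expect_equal(unname(tv$t), 3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_identical(tv$dof, 4L)

  # formula oracle on random data via stats::t.test (equal variances)
  set.seed(41)
  m2 <- log_em(matrix(rnorm(20 * 12, mean = 5), 20, 12))
  tv2 <- two_population_t(m2, 1:5, 6:12)
  for (n in c(1, 7, 20)) {
    oracle <- stats::t.test(m2$values[n, 6:12], m2$values[n, 1:5],
                            var.equal = TRUE)$statistic
    expect_equal(unname(tv2$t[n]), unname(oracle), tolerance = 1e-10)
  }

  # antisymmetry and the identical-group zero
  tv2r <- two_population_t(m2, 6:12, 1:5)
  expect_equal(tv2r$t, -tv2$t, tolerance = 1e-12)
  m3 <- log_em(cbind(matrix(1:4, 4, 2), matrix(1:4, 4, 2) + c(0, 1, 0, 1)))
  expect_error(two_population_t(log_em(matrix(2, 3, 4)), 1:2, 3:4),
               "zero pooled variance")
  expect_error(two_population_t(m2, 1:5, 5:8), "disjoint")
})

test_that("single-patient statistic is the singleton-group pooled t", {
  set.seed(42)
  m <- log_em(matrix(rnorm(30 * 10, mean = 6), 30, 10))
  z <- single_patient_t(m, patient = 1, reference_group = 2:10)
  tv <- two_population_t(m, groupA = 2:10, groupB = 1)
  expect_equal(unname(z), unname(tv$t), tolerance = 1e-12)

  # patient equal to the reference mean scores zero
  mref <- m$values[, 2:10]
  mc <- log_em(cbind(rowMeans(mref), mref))
  expect_equal(max(abs(single_patient_t(mc, 1, 2:10))), 0, tolerance = 1e-12)

  # patient at mean + 2 sd scores ~2 for a large reference
  set.seed(43)
  big <- matrix(rnorm(5 * 2000, mean = 5), 5, 2000)
  pat <- rowMeans(big) + 2 * apply(big, 1, sd)
  mb <- log_em(cbind(pat, big))
  expect_equal(unname(single_patient_t(mb, 1, 2:2001)), rep(2, 5),
               tolerance = 0.01)
  expect_error(single_patient_t(m, 1, c(1, 2, 3)), "exclude")
})

test_that("ccdf evaluation counts exceedances on the grid", {
  ens <- ccdf_ensemble(function(i) c(1, 2, 3), grid = c(0, 1.5, 2.5, 4), R = 1)
  expect_equal(as.numeric(ens$per_draw), c(1, 2 / 3, 1 / 3, 0))
  expect_error(ccdf_ensemble(function(i) 1, grid = numeric(0), R = 1),
               "non-empty")

  # Gaussian oracle: empirical ccdf of standard-normal statistics
  set.seed(44)
  N <- 50000
  ens2 <- ccdf_ensemble(function(i) rnorm(N), grid = seq(-2, 2, by = 0.5), R = 1)
  phi_bar <- pnorm(seq(-2, 2, by = 0.5), lower.tail = FALSE)
  tol <- 3 * sqrt(phi_bar * (1 - phi_bar) / N)
  expect_true(all(abs(ens2$mean_curve - phi_bar) <= pmax(tol, 1e-3)))

  # structural invariants on a stochastic ensemble
  set.seed(45)
  ens3 <- ccdf_ensemble(function(i) rnorm(500), grid = seq(-3, 3, 0.25), R = 40)
  for (i in 1:40) {
    expect_true(all(diff(ens3$per_draw[i, ]) <= 0))
    expect_true(all(ens3$per_draw[i, ] >= 0 & ens3$per_draw[i, ] <= 1))
  }
  expect_true(all(ens3$band_lo <= ens3$mean_curve + 1e-12))
  expect_true(all(ens3$mean_curve <= ens3$band_hi + 1e-12))
})

test_that("single-draw ROC matches a hand-enumerated curve", {
  # positives t = {5, 3, 1}, negatives t = {4, 2, 0}: descending ranking is
  # P N P N P N, so TPR steps 1/3 at FPR 0, 2/3 at 1/3, 1 at 2/3
  grid <- c(0, 0.2, 1 / 3, 0.5, 2 / 3, 0.9, 1)
  ens <- roc_ensemble(function(i) c(5, 3, 1), function(i) c(4, 2, 0),
                      fpr_grid = grid, R = 1)
  expect_equal(as.numeric(ens$per_draw),
               c(1 / 3, 1 / 3, 2 / 3, 2 / 3, 1, 1, 1))

  # perfect separation: TPR = 1 everywhere, including FPR 0
  ens2 <- roc_ensemble(function(i) c(10, 9), function(i) c(1, 2),
                       fpr_grid = grid, R = 1)
  expect_equal(as.numeric(ens2$per_draw), rep(1, length(grid)))

  expect_error(roc_ensemble(function(i) numeric(0), function(i) 1,
                            fpr_grid = grid, R = 1), "no positives")
})

test_that("null ROC ensembles hug the diagonal", {
  set.seed(46)
  grid <- seq(0, 1, by = 0.01)
  ens <- roc_ensemble(function(i) rnorm(1000), function(i) rnorm(1000),
                      fpr_grid = grid, R = 50)
  expect_lt(max(abs(ens$mean_curve - grid)), 0.08)
  for (i in 1:50) expect_true(all(diff(ens$per_draw[i, ]) >= 0))
  expect_true(all(ens$band_lo <= ens$band_hi))
})

test_that("multigene sum distributions equal exact convolutions", {
  # two-point distribution {0: 1/2, 1: 1/2}, k = 2
  d2 <- multigene_sum_distribution(c(0, 1), k = 2, bin_width = 1)
  expect_equal(d2$bin_grid, c(0, 1, 2))
  expect_equal(d2$probabilities, c(0.25, 0.5, 0.25))

  # point mass stays a point mass
  dp <- multigene_sum_distribution(rep(0.5, 10), k = 5, bin_width = 0.1)
  expect_equal(sum(dp$probabilities > 0), 1L)
  expect_equal(dp$bin_grid[which(dp$probabilities > 0)], 2.5)

  # k = 3 on a 5-point toy matches brute-force enumeration over 5^3 outcomes
  tvals <- c(-0.2, 0, 0.1, 0.3, 0.3)
  d3 <- multigene_sum_distribution(tvals, k = 3, bin_width = 0.1)
  sums <- as.vector(outer(as.vector(outer(tvals, tvals, "+")), tvals, "+"))
  oracle_idx <- round(sums / 0.1)
  got <- d3$probabilities[match(round(d3$bin_grid / 0.1), sort(unique(oracle_idx)))]
  oracle_p <- as.numeric(table(oracle_idx)) / 125
  keep <- d3$probabilities > 0
  expect_equal(d3$probabilities[keep],
               oracle_p[match(round(d3$bin_grid[keep] / 0.1),
                              sort(unique(oracle_idx)))],
               tolerance = 1e-12)
  expect_equal(sum(d3$probabilities), 1, tolerance = 1e-9)

  # k = 1 reproduces the binned input; mean and variance scale with k
  set.seed(47)
  tv <- rnorm(500)
  d1 <- multigene_sum_distribution(tv, k = 1)
  m1 <- sum(d1$bin_grid * d1$probabilities)
  v1 <- sum(d1$bin_grid^2 * d1$probabilities) - m1^2
  d4 <- multigene_sum_distribution(tv, k = 4)
  m4 <- sum(d4$bin_grid * d4$probabilities)
  v4 <- sum(d4$bin_grid^2 * d4$probabilities) - m4^2
  expect_equal(m4, 4 * m1, tolerance = 1e-8)
  expect_equal(v4, 4 * v1, tolerance = 1e-6)
  expect_error(multigene_sum_distribution(tv, k = 0), ">= 1")
})

test_that("multigene ROC sweeps thresholds over the sum distributions", {
  set.seed(48)
  tv <- rnorm(2000)
  dnull <- multigene_sum_distribution(tv, k = 2)
  dspike <- multigene_sum_distribution(tv + 10, k = 2)
  grid <- seq(0, 1, by = 0.01)

  # identical distributions give the diagonal (within bin resolution)
  same <- multigene_roc(dnull, dnull, grid)
  expect_lt(max(abs(same$tpr - same$fpr)), max(dnull$probabilities) + 1e-9)

  # disjoint shifted support gives TPR 1 at all FPR
  sep <- multigene_roc(dspike, dnull, grid)
  expect_true(all(sep$tpr == 1))

  # toy threshold-enumeration oracle
  ds <- multigene_sum_distribution(c(1, 2, 2, 3), k = 1, bin_width = 1)
  dn <- multigene_sum_distribution(c(0, 1, 2, 2), k = 1, bin_width = 1)
  r <- multigene_roc(ds, dn, fpr_grid = c(0, 0.25, 0.5, 0.75, 1))
  # thresholds (descending bins): >=3 -> (0, .25); >=2 -> (.5, .75); >=1 -> (.75, 1); >=0 -> (1,1)
  expect_equal(r$tpr, c(0.25, 0.25, 0.75, 1, 1))

  dn2 <- multigene_sum_distribution(c(0, 1), k = 1, bin_width = 0.5)
  expect_error(multigene_roc(ds, dn2), "grid mismatch")
})

test_that("detection rate increases with expression when low genes are noisy", {
  # mean-linked sd: noisier at low expression, so harder to detect there
  cfg <- synthetic_config(n_genes = 1600, n_samples = 60,
                          gene_sd = function(mu) 1.1 - 0.08 * mu,
                          distortion = "identity", noise_sd = 0, seed = 55)
  m <- generate_synthetic_dataset(cfg)$measured
  des <- spike_design(1:20, seq_len(1600), 40)
  out <- detection_rate_by_expression(m, des, t_threshold = 3, block = 400,
                                      R = 30, seed = 56)
  expect_identical(nrow(out), 4L)
  expect_true(all(diff(out$detection_rate) > 0))

  # degenerate thresholds
  z <- detection_rate_by_expression(m, spike_design(1:20, 1:1600, 0),
                                    t_threshold = Inf, block = 400, R = 2,
                                    seed = 1)
  expect_true(all(z$detection_rate == 0))
  h <- detection_rate_by_expression(m, spike_design(1:20, 1:1600, 700),
                                    t_threshold = 0, block = 400, R = 2,
                                    seed = 1)
  expect_gt(mean(h$detection_rate), 0.95)
})

test_that("Spearman correlation distributions behave at the null and for ties", {
  # monotone dependence gives rho = 1
  m <- log_em(cbind(1:6, c(2, 4, 5, 7, 8, 9)))
  mm <- expression_matrix(t(m$values), c("s1", "s2"), sprintf("p%d", 1:6),
                          scale = "log2_offset", offset_c = 0.25)
  cd <- correlation_distribution(mm)
  expect_equal(cd$correlations, 1)

  # tied ranks use average ranks
  mt <- expression_matrix(rbind(c(1, 1, 2), c(1, 2, 3)), c("a", "b"),
                          c("x", "y", "z"), scale = "log2_offset",
                          offset_c = 0.25)
  ct <- correlation_distribution(mt)
  expect_equal(ct$correlations, sqrt(0.75), tolerance = 1e-12)

  # scrambled independent genes: centered at 0 with sd ~ 1/sqrt(M-1)
  M <- 80
  m2 <- scramble_genes(random_log_em(150, M, seed = 61), seed = 62)
  cd2 <- correlation_distribution(m2, n_pairs = 2000, seed = 63)
  expect_equal(cd2$mean, 0, tolerance = 0.02)
  expect_equal(cd2$sd, 1 / sqrt(M - 1), tolerance = 0.2 / sqrt(M - 1))

  # constant genes are skipped and counted
  mc <- log_em(rbind(rep(5, 10), matrix(rnorm(40, 5), 4, 10)))
  cdc <- correlation_distribution(mc)
  expect_identical(cdc$n_skipped, 4L)
})

test_that("correlation differences detect per-sample rank-breaking transforms", {
  mA <- random_log_em(80, 40, seed = 71)
  same <- correlation_difference_distribution(mA, mA, n_pairs = 200, seed = 72)
  expect_true(all(same$differences == 0))

  # apply a different monotone warp to each sample: across-gene ranks within a
  # sample are preserved, but across-sample ranks per gene break
  warped <- sapply(seq_len(40), function(j) {
    g <- mA$values[, j]
    g + 0.15 * j / 40 * (g - mean(g))^2 / 4
  })
  mB <- expression_matrix(warped, gene_ids(mA), sample_ids(mA),
                          scale = "log2_offset", offset_c = 0.25)
  diff <- correlation_difference_distribution(mA, mB, n_pairs = 300, seed = 73)
  expect_gt(sd(diff$differences), 0)

  # mean-range restriction matches a brute-force pair filter
  pairs <- diff$pairs
  means <- rowMeans(mA$values)
  keep <- means[pairs[, 1]] >= 4 & means[pairs[, 1]] <= 5 &
    means[pairs[, 2]] >= 4 & means[pairs[, 2]] <= 5
  restricted <- correlation_difference_distribution(mA, mB, pairs = pairs,
                                                    mean_range = c(4, 5))
  expect_identical(nrow(restricted$pairs), sum(keep))
  expect_identical(restricted$pairs, pairs[keep, , drop = FALSE])

  mC <- random_log_em(79, 40, seed = 74)
  expect_error(correlation_difference_distribution(mA, mC, n_pairs = 10,
                                                   seed = 1),
               "different gene sets")
})
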