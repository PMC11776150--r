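#' @name evaluation
#' @title Resampled evaluation of correction effects on statistical tests
#' @description Pooled-variance t statistics, resampled complementary-CDF and
#' averaged ROC ensembles with 10th/90th percentile bands, multigene
#' convolution tests, single-patient tests, detection rate by expression
#' level, and gene-gene Spearman correlation distributions.
NULL

# resolve a group given as indices or sample ids to integer indices
.resolve_samples <- function(m, g) {
  if (is.character(g)) {
    idx <- match(g, sample_ids(m))
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(g[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(g)
}

# fast pooled-variance row t statistics; returns (meanB - meanA) / se
.row_t <- function(values, iA, iB) {
  nA <- length(iA); nB <- length(iB)
  xA <- values[, iA, drop = FALSE]; xB <- values[, iB, drop = FALSE]
  mA <- rowMeans(xA); mB <- rowMeans(xB)
  ssA <- if (nA > 1L) rowSums((xA - mA)^2) else numeric(nrow(values))
  ssB <- if (nB > 1L) rowSums((xB - mB)^2) else numeric(nrow(values))
  sp2 <- (ssA + ssB) / (nA + nB - 2L)
  (mB - mA) / sqrt(sp2 * (1 / nA + 1 / nB))
}

#' Two-population pooled-variance t statistics
#'
#' Per gene, \eqn{t = (\bar x_B - \bar x_A) / (s_p \sqrt{1/n_A + 1/n_B})} with
#' the pooled variance \eqn{s_p^2 = ((n_A-1)s_A^2 + (n_B-1)s_B^2)/(n_A+n_B-2)}
#' (equal variances assumed). Per-gene standardization happens here and only
#' here, after any bias correction.
#'
#' @param m A log2-offset-scale `ExpressionMatrix`.
#' @param groupA,groupB Disjoint, non-empty sample index (or id) vectors.
#' @return A `TStatVector`: list with `t` (named per-gene statistics), `dof`
#'   (`nA + nB - 2`) and `group_sizes`.
#' @export
two_population_t <- function(m, groupA, groupB) {
  .assert_em(m, "log2_offset")
  iA <- .resolve_samples(m, groupA); iB <- .resolve_samples(m, groupB)
  if (length(iA) == 0L || length(iB) == 0L) stop("groups must be non-empty")
  if (length(intersect(iA, iB)) > 0L) stop("groups must be disjoint")
  if (length(iA) + length(iB) < 3L) stop("need at least 3 samples in total")
  t <- .row_t(m$values, iA, iB)
  if (any(!is.finite(t))) {
    bad <- gene_ids(m)[which(!is.finite(t))[1]]
    stop("zero pooled variance for gene '", bad, "'")
  }
  names(t) <- gene_ids(m)
  structure(list(t = t, dof = length(iA) + length(iB) - 2L,
                 group_sizes = c(nA = length(iA), nB = length(iB))),
            class = "TStatVector")
}

#' @export
print.TStatVector <- function(x, ...) {
  cat(sprintf("TStatVector: %d genes, groups (%d, %d), dof %d\n",
              length(x$t), x$group_sizes[1], x$group_sizes[2], x$dof))
  invisible(x)
}

#' Single-patient statistic against a reference population
#'
#' Per gene, \eqn{z = (g_{n,\mathrm{patient}} - \bar x_{\mathrm{ref}})
#' / (s_{\mathrm{ref}} \sqrt{1 + 1/n_{\mathrm{ref}}})} -- the two-population
#' pooled t with a singleton group (the patient contributes no variance).
#'
#' @param m A log2-offset-scale `ExpressionMatrix`.
#' @param patient A single sample index or id.
#' @param reference_group Sample indices/ids excluding the patient, size >= 2.
#' @return Named numeric vector of per-gene statistics.
#' @export
single_patient_t <- function(m, patient, reference_group) {
  .assert_em(m, "log2_offset")
  ip <- .resolve_samples(m, patient)
  ir <- .resolve_samples(m, reference_group)
  if (length(ip) != 1L) stop("'patient' must be a single sample")
  if (ip %in% ir) stop("reference group must exclude the patient")
  if (length(ir) < 2L) stop("reference group must have at least 2 samples")
  xr <- m$values[, ir, drop = FALSE]
  mr <- rowMeans(xr)
  sr <- sqrt(rowSums((xr - mr)^2) / (length(ir) - 1L))
  if (any(sr == 0)) {
    bad <- gene_ids(m)[which(sr == 0)[1]]
    stop("zero reference variance for gene '", bad, "'")
  }
  z <- (m$values[, ip] - mr) / (sr * sqrt(1 + 1 / length(ir)))
  stats::setNames(z, gene_ids(m))
}

.new_ensemble <- function(kind, grid, per_draw, R, seed) {
  structure(list(curve_kind = kind, grid = grid, per_draw = per_draw,
                 mean_curve = colMeans(per_draw),
                 band_lo = apply(per_draw, 2L, stats::quantile, probs = 0.1,
                                 names = FALSE),
                 band_hi = apply(per_draw, 2L, stats::quantile, probs = 0.9,
                                 names = FALSE),
                 R = R, seed = seed),
            class = "ResamplingEnsemble")
}

#' @export
print.ResamplingEnsemble <- function(x, ...) {
  cat(sprintf("ResamplingEnsemble: %s over %d draws, grid of %d points\n",
              x$curve_kind, x$R, length(x$grid)))
  invisible(x)
}

#' Plot a resampling ensemble
#'
#' Mean curve with the 10th/90th percentile band.
#'
#' @param x A `ResamplingEnsemble`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ResamplingEnsemble <- function(x, ...) {
  xlab <- if (x$curve_kind == "roc") "FPR" else "t"
  ylab <- if (x$curve_kind == "roc") "TPR" else "ccdf"
  graphics::plot(x$grid, x$mean_curve, type = "l", xlab = xlab, ylab = ylab,
                 ylim = range(x$band_lo, x$band_hi), ...)
  graphics::lines(x$grid, x$band_lo, lty = 3)
  graphics::lines(x$grid, x$band_hi, lty = 3)
  invisible(x)
}

#' Resampled complementary-CDF ensemble
#'
#' Per draw, evaluates the ccdf of a statistic vector -- the fraction of
#' genes whose statistic strictly exceeds each grid value -- and summarizes
#' the draws by their mean curve and 10th/90th percentile band.
#'
#' @param runner Function of the draw index returning a numeric vector of
#'   statistics (a `TStatVector` is also accepted).
#' @param grid Non-empty increasing vector of t thresholds.
#' @param R Number of draws (>= 1).
#' @param seed Optional seed set once before the draw loop.
#' @return A `ResamplingEnsemble` with `curve_kind = "ccdf"`.
#' @export
ccdf_ensemble <- function(runner, grid, R, seed = NULL) {
  if (length(grid) == 0L) stop("'grid' must be non-empty")
  if (R < 1L) stop("'R' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  per_draw <- matrix(NA_real_, R, length(grid))
  for (i in seq_len(R)) {
    tv <- runner(i)
    if (inherits(tv, "TStatVector")) tv <- tv$t
    st <- sort(tv)
    # fraction strictly greater than each grid point
    per_draw[i, ] <- 1 - findInterval(grid, st) / length(st)
  }
  .new_ensemble("ccdf", grid, per_draw, R, seed)
}

# empirical ROC operating points from positive/negative scores, descending
# threshold sweep; tied scores are collapsed into a single operating point
.roc_points <- function(pos, neg) {
  scores <- c(pos, neg)
  labels <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; lab <- labels[o]
  tp <- cumsum(lab); fp <- cumsum(1L - lab)
  keep <- c(diff(s) != 0, TRUE)     # last index of each tied run
  fpr <- c(0, fp[keep] / length(neg))
  tpr <- c(0, tp[keep] / length(pos))
  # one point per distinct FPR: the highest TPR attained there
  last <- !duplicated(fpr, fromLast = TRUE)
  list(fpr = fpr[last], tpr = tpr[last])
}

# step interpolation of TPR as a function of FPR on a grid
.roc_on_grid <- function(pts, fpr_grid) {
  stats::approx(pts$fpr, pts$tpr, xout = fpr_grid, method = "constant",
                f = 0, rule = 2, ties = "ordered")$y
}

#' Resampled averaged ROC ensemble
#'
#' Per draw, builds the empirical ROC by ranking gene statistics: positives
#' are the statistics of spiked genes from the spiked computation, negatives
#' the statistics from the matched null (unspiked) computation on the same
#' subpopulation split. Each draw's ROC is expressed as TPR at each FPR grid
#' point by step interpolation; the ensemble reports the mean TPR curve and
#' the 10th/90th percentile band across draws ("method 2" averaging: TPR as a
#' function of FPR, appropriate when a fixed number of top-ranked genes sets
#' the FPR).
#'
#' @param spiked_runner,null_runner Functions of the draw index returning
#'   statistic vectors for the spiked and the matched null computation; the
#'   pairing per replicate (same split) is the caller's responsibility.
#' @param fpr_grid Increasing FPR grid in \[0, 1\] (default 0..1 step 0.001).
#' @param R Number of draws.
#' @param seed Optional seed set once before the draw loop.
#' @return A `ResamplingEnsemble` with `curve_kind = "roc"`.
#' @export
roc_ensemble <- function(spiked_runner, null_runner,
                         fpr_grid = seq(0, 1, by = 0.001), R, seed = NULL) {
  if (length(fpr_grid) == 0L) stop("'fpr_grid' must be non-empty")
  if (R < 1L) stop("'R' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  per_draw <- matrix(NA_real_, R, length(fpr_grid))
  for (i in seq_len(R)) {
    sp <- spiked_runner(i); nu <- null_runner(i)
    if (inherits(sp, "TStatVector")) sp <- sp$t
    if (inherits(nu, "TStatVector")) nu <- nu$t
    if (length(sp) == 0L) stop("draw ", i, " produced no positives")
    if (length(nu) == 0L) stop("draw ", i, " produced no negatives")
    per_draw[i, ] <- .roc_on_grid(.roc_points(sp, nu), fpr_grid)
  }
  .new_ensemble("roc", fpr_grid, per_draw, R, seed)
}

#' Distribution of k-gene sums of t statistics
#'
#' Treats the genes as a probability space with weight 1/N each; the per-gene
#' t values define a distribution, histogrammed on a uniform grid of width
#' `bin_width`. The distribution of sums of k randomly chosen t values is the
#' k-fold discrete self-convolution, renormalized to sum to one (the grid is
#' extended so the k-fold support is not truncated).
#'
#' @param t A `TStatVector` or numeric vector of statistics.
#' @param k Genes per set (>= 1).
#' @param bin_width Histogram bin width in t units (default 0.01).
#' @return A `SumStatDistribution`: list with `n_genes_summed`, `bin_grid`
#'   (bin centers), `probabilities` and `bin_width`.
#' @export
multigene_sum_distribution <- function(t, k, bin_width = 0.01) {
  if (inherits(t, "TStatVector")) t <- t$t
  if (k < 1L) stop("'k' must be >= 1")
  if (bin_width <= 0) stop("'bin_width' must be positive")
  idx <- round(t / bin_width)
  i0 <- min(idx); i1 <- max(idx)
  p <- tabulate(idx - i0 + 1L, nbins = i1 - i0 + 1L) / length(idx)
  pk <- p; lo <- i0
  if (k > 1L) for (j in 2:k) { pk <- .polymul(pk, p); lo <- lo + i0 }
  pk <- pk / sum(pk)
  structure(list(n_genes_summed = as.integer(k),
                 bin_grid = (lo + seq_along(pk) - 1L) * bin_width,
                 probabilities = pk, bin_width = bin_width),
            class = "SumStatDistribution")
}

#' ROC curve for multigene sum statistics
#'
#' Sweeps a detection threshold over the sum-statistic grid: at each
#' threshold the FPR is the null distribution's ccdf and the TPR the spiked
#' distribution's ccdf; the resulting curve is reported as TPR at each FPR
#' grid point by step interpolation. Both distributions must share the same
#' bin width; their supports are aligned internally.
#'
#' @param spiked_dist,null_dist `SumStatDistribution` objects with equal bin
#'   widths.
#' @param fpr_grid Increasing FPR grid (default 0..1 step 0.001).
#' @return Data frame with columns `fpr` and `tpr`.
#' @export
multigene_roc <- function(spiked_dist, null_dist,
                          fpr_grid = seq(0, 1, by = 0.001)) {
  if (!inherits(spiked_dist, "SumStatDistribution") ||
      !inherits(null_dist, "SumStatDistribution"))
    stop("expected SumStatDistribution inputs")
  if (abs(spiked_dist$bin_width - null_dist$bin_width) >
      1e-12 * spiked_dist$bin_width)
    stop("grid mismatch: the two distributions have different bin widths")
  bw <- spiked_dist$bin_width
  i_s <- round(spiked_dist$bin_grid / bw)
  i_n <- round(null_dist$bin_grid / bw)
  lo <- min(i_s[1], i_n[1]); hi <- max(i_s[length(i_s)], i_n[length(i_n)])
  ps <- pn <- numeric(hi - lo + 1L)
  ps[i_s - lo + 1L] <- spiked_dist$probabilities
  pn[i_n - lo + 1L] <- null_dist$probabilities
  # P(stat >= bin) per bin; traversing bins from the top down sweeps the
  # threshold downwards, so FPR and TPR are both nondecreasing
  tpr_pts <- cumsum(rev(ps))
  fpr_pts <- cumsum(rev(pn))
  fpr <- c(0, fpr_pts); tpr <- c(0, tpr_pts)
  last <- !duplicated(fpr, fromLast = TRUE)   # max TPR at each distinct FPR
  pts <- list(fpr = fpr[last], tpr = tpr[last])
  data.frame(fpr = fpr_grid, tpr = .roc_on_grid(pts, fpr_grid))
}

#' Detection rate by mean expression level
#'
#' Over R random subpopulation draws (size taken from the design), spikes the
#' design's genes in the drawn subpopulation, computes two-population t
#' statistics against the complement, and records the fraction of draws in
#' which each spiked gene exceeds `t_threshold`. Rates are averaged within
#' blocks of `block` consecutive spiked genes sorted by mean expression.
#'
#' @param m A log2-offset-scale `ExpressionMatrix`.
#' @param design A [spike_design()] (its `subpopulation` sets the draw size).
#' @param t_threshold Detection threshold on the t statistic.
#' @param block Genes per averaging block (default 800).
#' @param R Number of draws.
#' @param seed Integer seed.
#' @return Data frame with columns `block`, `mean_expression` and
#'   `detection_rate`.
#' @export
detection_rate_by_expression <- function(m, design, t_threshold, block = 800L,
                                         R, seed) {
  .assert_em(m, "log2_offset")
  if (!inherits(design, "SpikeDesign")) stop("expected a SpikeDesign")
  N <- nrow(m$values); M <- ncol(m$values)
  if (block > N) stop("'block' exceeds the number of genes")
  P <- length(design$subpopulation)
  genes <- design$spiked_genes
  set.seed(seed)
  hits <- numeric(length(genes))
  for (i in seq_len(R)) {
    sub <- sample.int(M, P)
    vals <- m$values
    vals[genes, sub] <- vals[genes, sub] + design$log_shift
    tv <- .row_t(vals, setdiff(seq_len(M), sub), sub)
    hits <- hits + (tv[genes] > t_threshold)
  }
  rates <- hits / R
  means <- rowMeans(m$values)[genes]
  o <- order(means, gene_ids(m)[genes])
  nb <- length(genes) %/% block
  if (nb < 1L) stop("fewer spiked genes than one block")
  idx <- o[seq_len(nb * block)]
  f <- rep(seq_len(nb), each = block)
  data.frame(block = seq_len(nb),
             mean_expression = as.numeric(rowsum(means[idx], f)) / block,
             detection_rate = as.numeric(rowsum(rates[idx], f)) / block)
}

# Spearman correlations for a 2-column matrix of gene-index pairs, from
# pre-standardized average-rank rows; rows with zero rank variance are NA
.pair_spearman <- function(values, pairs) {
  M <- ncol(values)
  Rk <- t(apply(values, 1L, rank))    # average ranks for ties
  mu <- rowMeans(Rk)
  ss <- sqrt(rowSums((Rk - mu)^2))
  ok <- ss > 0
  Z <- (Rk - mu) / ifelse(ss > 0, ss, 1)
  rho <- unname(rowSums(Z[pairs[, 1L], , drop = FALSE] *
                          Z[pairs[, 2L], , drop = FALSE]))
  rho[!ok[pairs[, 1L]] | !ok[pairs[, 2L]]] <- NA_real_
  rho
}

# sample n distinct unordered gene pairs (without replacement among pairs)
.sample_pairs <- function(N, n_pairs) {
  total <- N * (N - 1) / 2
  n_pairs <- min(n_pairs, total)
  # rejection sampling of unordered pairs; fine for n_pairs << N^2
  seen <- new.env(hash = TRUE)
  out <- matrix(0L, n_pairs, 2L)
  k <- 0L
  while (k < n_pairs) {
    i <- sample.int(N, 1L); j <- sample.int(N, 1L)
    if (i == j) next
    a <- min(i, j); b <- max(i, j)
    key <- paste0(a, "_", b)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    k <- k + 1L
    out[k, ] <- c(a, b)
  }
  out
}

#' Distribution of gene-gene Spearman correlations
#'
#' Spearman rank correlation (average ranks for ties) across samples for each
#' sampled gene pair. Pairs containing a constant gene are skipped and
#' counted. Uncorrected expression-level-dependent bias inflates and shifts
#' this distribution; corrections should center it.
#'
#' @param m An `ExpressionMatrix` with at least 3 samples.
#' @param n_pairs Number of random gene pairs, or `NULL` for all pairs.
#' @param seed Seed for pair sampling (required when `n_pairs` is given).
#' @return List with `correlations`, `mean`, `sd`, `n_skipped` and `pairs`
#'   (the 2-column index matrix).
#' @export
correlation_distribution <- function(m, n_pairs = NULL, seed = NULL) {
  .assert_em(m)
  N <- nrow(m$values)
  if (ncol(m$values) < 3L) stop("at least 3 samples are required")
  pairs <- if (is.null(n_pairs)) {
    if (N > 3000L) stop("all-pairs correlation on > 3000 genes; pass 'n_pairs'")
    cbind(rep(seq_len(N - 1L), times = (N - 1L):1L),
          unlist(lapply(seq_len(N - 1L), function(i) (i + 1L):N)))
  } else {
    if (is.null(seed)) stop("'seed' is required when sampling pairs")
    set.seed(seed)
    .sample_pairs(N, n_pairs)
  }
  rho <- .pair_spearman(m$values, pairs)
  skipped <- sum(is.na(rho))
  rho_ok <- rho[!is.na(rho)]
  list(correlations = rho_ok, mean = mean(rho_ok), sd = stats::sd(rho_ok),
       n_skipped = skipped, pairs = pairs)
}

#' Distribution of per-pair correlation differences between two matrices
#'
#' For a shared pair list, computes the Spearman correlation of each pair in
#' both matrices and returns the per-pair difference
#' \eqn{\rho_A - \rho_B}. Optionally restricts to pairs whose two genes both
#' have mean expression (computed on `mA`) inside `mean_range` -- genes with
#' similar expression experience similar per-sample bias, so restricting the
#' range amplifies the corruption that correction should remove.
#'
#' @param mA,mB `ExpressionMatrix` objects with identical gene sets.
#' @param pairs 2-column integer matrix of gene index pairs (indices into
#'   `mA`'s gene order), or `NULL` with `n_pairs`/`seed` to sample.
#' @param n_pairs,seed Pair sampling, as in [correlation_distribution()].
#' @param mean_range Optional length-2 interval for the mean-expression
#'   restriction.
#' @return List with `differences`, `mean`, `sd`, `pairs` (the pairs used)
#'   and `n_skipped`.
#' @export
correlation_difference_distribution <- function(mA, mB, pairs = NULL,
                                                n_pairs = NULL, seed = NULL,
                                                mean_range = NULL) {
  .assert_em(mA); .assert_em(mB)
  if (!identical(gene_ids(mA), gene_ids(mB))) {
    if (!setequal(gene_ids(mA), gene_ids(mB)))
      stop("the two matrices have different gene sets")
    # same set, different order: align B to A
    mB <- expression_matrix(mB$values[gene_ids(mA), , drop = FALSE],
                            gene_ids(mA), sample_ids(mB),
                            scale = mB$scale, offset_c = mB$offset_c)
  }
  N <- nrow(mA$values)
  if (is.null(pairs)) {
    if (is.null(n_pairs) || is.null(seed))
      stop("provide 'pairs', or 'n_pairs' and 'seed'")
    set.seed(seed)
    pairs <- .sample_pairs(N, n_pairs)
  }
  if (!is.null(mean_range)) {
    means <- rowMeans(mA$values)
    inside <- means >= mean_range[1] & means <= mean_range[2]
    pairs <- pairs[inside[pairs[, 1L]] & inside[pairs[, 2L]], , drop = FALSE]
    if (nrow(pairs) == 0L) stop("no gene pairs inside 'mean_range'")
  }
  rA <- .pair_spearman(mA$values, pairs)
  rB <- .pair_spearman(mB$values, pairs)
  d <- rA - rB
  skipped <- sum(is.na(d))
  d <- d[!is.na(d)]
  list(differences = d, mean = mean(d), sd = stats::sd(d),
       pairs = pairs, n_skipped = skipped)
}
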