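#' Synthetic dataset configuration
#'
#' Describes the generative model for synthetic expression data with known
#' ground truth, emulating the statistical shape of preprocessed bulk RNA-seq
#' log2 matrices: per-gene true mean levels spanning several log2 units,
#' across-sample variability roughly independent of the mean, optional
#' equicorrelated gene blocks, per-sample polynomial scale distortions, and
#' additive residual noise.
#'
#' Measured data are generated in the forward direction
#' \eqn{g_{nm} = p_m(G_{nm}) + \epsilon_{nm}}: truth, distort, add noise.
#' The default distortion (`"gentle_cubic"`) draws per-sample cubics with
#' \eqn{|p_m(g) - g| \le 0.3} over the expression range, the magnitude of
#' distortions observed in real cohorts.
#'
#' @param n_genes Number of genes N (default 8000).
#' @param n_samples Number of samples M (default 400).
#' @param mean_range Range of true per-gene log2 means, uniform (default
#'   `c(3, 12)`).
#' @param gene_sd Per-gene across-sample sd: a scalar (default 0.5, flat
#'   mean-variance profile), a length-N vector, or a function of the gene
#'   mean (mean-linked variability).
#' @param correlation_block_size Optional block size for equicorrelated gene
#'   blocks (`NULL` = independent genes).
#' @param rho Within-block correlation, `|rho| < 1` (default 0).
#' @param distortion `"gentle_cubic"` (default), `"identity"`, or a list of
#'   per-sample ascending coefficient vectors (length 1 recycled, or M).
#' @param noise_sd Sd of the additive residual noise (default 0.1).
#' @param seed Integer seed; every draw is a pure function of the config.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_genes = 8000L, n_samples = 400L,
                             mean_range = c(3, 12), gene_sd = 0.5,
                             correlation_block_size = NULL, rho = 0,
                             distortion = "gentle_cubic", noise_sd = 0.1,
                             seed = 1L) {
  if (n_genes < 1L || n_samples < 1L) stop("'n_genes' and 'n_samples' must be >= 1")
  if (length(mean_range) != 2L || mean_range[2] < mean_range[1])
    stop("'mean_range' must be an increasing length-2 range")
  if (is.numeric(gene_sd) && any(gene_sd < 0)) stop("'gene_sd' must be >= 0")
  if (abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1")
  if (rho != 0 && is.null(correlation_block_size))
    stop("'correlation_block_size' is required when rho != 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (is.character(distortion)) {
    distortion <- match.arg(distortion, c("gentle_cubic", "identity"))
  } else if (is.list(distortion)) {
    if (!length(distortion) %in% c(1L, n_samples))
      stop("'distortion' list must have length 1 or n_samples")
  } else stop("'distortion' must be a keyword or a list of coefficient vectors")
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 mean_range = mean_range, gene_sd = gene_sd,
                 correlation_block_size = correlation_block_size, rho = rho,
                 distortion = distortion, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# draw per-sample gentle cubic distortions p_m(g) = g + d_m(u), where
# u = (g - mid)/half and d_m has 4 coefficients each uniform on
# (-0.075, 0.075), so |d_m| <= 0.3 on the range; raw-basis coefficients
.draw_distortions <- function(cfg) {
  M <- cfg$n_samples
  if (is.list(cfg$distortion)) {
    ps <- rep(cfg$distortion, length.out = M)
    return(ps)
  }
  if (cfg$distortion == "identity") {
    return(rep(list(c(0, 1)), M))
  }
  mid <- mean(cfg$mean_range)
  half <- diff(cfg$mean_range) / 2 + 2   # covers excursions beyond the mean range
  lapply(seq_len(M), function(j) {
    cu <- stats::runif(4L, -0.075, 0.075)
    p <- .rebase_poly(cu, mid, half)     # d_m as a polynomial in g
    p[2] <- p[2] + 1                     # add the identity term
    p
  })
}

#' Generate a synthetic dataset with known ground truth
#'
#' @param cfg A [synthetic_config()].
#' @return List with `truth` and `measured` (`ExpressionMatrix` objects on the
#'   log2 scale), and `config` (the input config with the realized
#'   `distortion_polynomials` attached).
#' @export
generate_synthetic_dataset <- function(cfg) {
  if (!inherits(cfg, "SyntheticConfig")) stop("expected a SyntheticConfig")
  set.seed(cfg$seed)
  N <- cfg$n_genes; M <- cfg$n_samples
  gbar_true <- stats::runif(N, cfg$mean_range[1], cfg$mean_range[2])
  sdv <- if (is.function(cfg$gene_sd)) cfg$gene_sd(gbar_true)
         else rep_len(cfg$gene_sd, N)
  if (is.null(cfg$correlation_block_size) || cfg$rho == 0) {
    E <- matrix(stats::rnorm(N * M), N, M)
  } else {
    cbs <- cfg$correlation_block_size
    blk <- ceiling(seq_len(N) / cbs)
    zb <- matrix(stats::rnorm(max(blk) * M), max(blk), M)
    E <- sqrt(cfg$rho) * zb[blk, , drop = FALSE] +
      sqrt(1 - cfg$rho) * matrix(stats::rnorm(N * M), N, M)
  }
  truth_vals <- gbar_true + sdv * E
  ps <- .draw_distortions(cfg)
  measured_vals <- vapply(seq_len(M),
                          function(j) .polyeval(ps[[j]], truth_vals[, j]),
                          numeric(N))
  if (cfg$noise_sd > 0)
    measured_vals <- measured_vals + matrix(stats::rnorm(N * M, sd = cfg$noise_sd), N, M)
  gids <- sprintf("g%05d", seq_len(N))
  sids <- sprintf("s%04d", seq_len(M))
  cfg$distortion_polynomials <- ps
  list(truth = expression_matrix(truth_vals, gids, sids,
                                 scale = "log2_offset", offset_c = 0.25),
       measured = expression_matrix(measured_vals, gids, sids,
                                    scale = "log2_offset", offset_c = 0.25),
       config = cfg)
}

#' Spike design
#'
#' Describes a controlled differential-expression injection: a C-percent
#' enhancement of the chosen genes in the chosen subpopulation, realized as an
#' additive log2 shift of \eqn{\log_2(1 + C/100)} (exactly multiplication by
#' `1 + C/100` on the raw scale when the log offset is zero, and within the
#' offset distortion bound otherwise).
#'
#' @param subpopulation Integer indices of the spiked samples.
#' @param spiked_genes Integer indices of the spiked genes.
#' @param spike_level_percent Spike level C in percent, `C >= 0`.
#' @return A `SpikeDesign` list with the derived `log_shift`.
#' @export
spike_design <- function(subpopulation, spiked_genes, spike_level_percent) {
  if (spike_level_percent < 0) stop("'spike_level_percent' must be >= 0")
  subpopulation <- as.integer(subpopulation)
  spiked_genes <- as.integer(spiked_genes)
  if (anyDuplicated(subpopulation) || anyDuplicated(spiked_genes))
    stop("spike indices must be distinct")
  structure(list(subpopulation = subpopulation, spiked_genes = spiked_genes,
                 spike_level_percent = spike_level_percent,
                 log_shift = log2(1 + spike_level_percent / 100)),
            class = "SpikeDesign")
}

#' Apply a spike design
#'
#' Adds the design's log2 shift to the entries at (spiked genes x
#' subpopulation); all other entries are untouched.
#'
#' @param m A log2-offset-scale `ExpressionMatrix`.
#' @param design A [spike_design()].
#' @return The spiked `ExpressionMatrix`.
#' @export
spike <- function(m, design) {
  .assert_em(m, "log2_offset")
  if (!inherits(design, "SpikeDesign")) stop("expected a SpikeDesign")
  N <- nrow(m$values); M <- ncol(m$values)
  if (any(design$subpopulation < 1L) || any(design$subpopulation > M))
    stop("subpopulation indices out of range")
  if (length(design$subpopulation) >= M)
    stop("subpopulation must be smaller than the number of samples")
  if (any(design$spiked_genes < 1L) || any(design$spiked_genes > N))
    stop("spiked gene indices out of range")
  vals <- m$values
  vals[design$spiked_genes, design$subpopulation] <-
    vals[design$spiked_genes, design$subpopulation] + design$log_shift
  expression_matrix(vals, gene_ids(m), sample_ids(m),
                    scale = m$scale, offset_c = m$offset_c)
}

#' Draw random subpopulations
#'
#' R independent uniform draws of P distinct sample indices out of M,
#' reproducible from the seed.
#'
#' @param M Total number of samples.
#' @param P Subpopulation size, `1 <= P < M`.
#' @param R Number of draws.
#' @param seed Integer seed.
#' @return List of R integer index vectors.
#' @export
draw_subpopulations <- function(M, P, R, seed) {
  if (P < 1L || P >= M) stop("'P' must satisfy 1 <= P < M")
  if (R < 1L) stop("'R' must be >= 1")
  set.seed(seed)
  lapply(seq_len(R), function(i) sample.int(M, P))
}

#' Scramble genes across samples
#'
#' Independently permutes each gene's values across samples, destroying
#' gene-gene correlation while preserving each gene's marginal distribution
#' exactly.
#'
#' @param m An `ExpressionMatrix`.
#' @param seed Integer seed.
#' @return The scrambled `ExpressionMatrix`.
#' @export
scramble_genes <- function(m, seed) {
  .assert_em(m)
  set.seed(seed)
  vals <- m$values
  M <- ncol(vals)
  if (M > 1L) {
    for (n in seq_len(nrow(vals))) vals[n, ] <- vals[n, sample.int(M)]
  }
  expression_matrix(vals, gene_ids(m), sample_ids(m),
                    scale = m$scale, offset_c = m$offset_c)
}

#' Matched independent Gaussian reference
#'
#' Generates an independent per-gene Gaussian matrix in which gene j has the
#' same sample mean and sd as gene j of the input (unbiased M-1 sd). Used as
#' the correlation-free, exactly-normal reference in ccdf/ROC comparisons.
#' Zero-sd genes become constant rows.
#'
#' @param m An `ExpressionMatrix` with at least 2 samples.
#' @param seed Integer seed.
#' @return An `ExpressionMatrix` of the same shape and ids.
#' @export
gaussian_reference <- function(m, seed) {
  .assert_em(m)
  N <- nrow(m$values); M <- ncol(m$values)
  if (M < 2L) stop("at least 2 samples are required")
  set.seed(seed)
  mu <- rowMeans(m$values)
  sdv <- sqrt(rowSums((m$values - mu)^2) / (M - 1))
  vals <- mu + sdv * matrix(stats::rnorm(N * M), N, M)
  expression_matrix(vals, gene_ids(m), sample_ids(m),
                    scale = m$scale, offset_c = m$offset_c)
}
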