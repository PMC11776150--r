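#' Per-gene mean expression
#'
#' The across-sample mean \eqn{\bar g_n = \frac{1}{M}\sum_m g_{nm}} on the
#' log2 scale; the consensus profile against which per-sample deviations and
#' the local-leveling correction are defined.
#'
#' @param m A log2-offset-scale `ExpressionMatrix`.
#' @return Named numeric vector, one mean per gene.
#' @export
gene_means <- function(m) {
  .assert_em(m, "log2_offset")
  rowMeans(m$values)
}

#' Per-gene deviations from the mean profile
#'
#' \eqn{\delta_{nm} = g_{nm} - \bar g_n}; each row sums to zero.
#'
#' @inheritParams gene_means
#' @return N x M numeric matrix of deviations.
#' @export
gene_deviations <- function(m) {
  .assert_em(m, "log2_offset")
  m$values - rowMeans(m$values)
}

# gene order sorted by increasing mean, ties broken by gene id (stable,
# reproducible across permutations of the input)
.mean_order <- function(m) {
  means <- rowMeans(m$values)
  order(means, gene_ids(m))
}

#' Per-sample block-deviation profile
#'
#' The core bias diagnostic. Genes are ordered (by increasing mean expression,
#' or randomly) and partitioned into `floor(N/B)` consecutive blocks of `B`
#' genes (trailing remainder dropped). The raw profile is the per-block,
#' per-sample mean \eqn{b_{km}}; the centered profile subtracts the across-
#' sample mean of each block, \eqn{\bar b_{km} = b_{km} - \frac1M \sum_{m'}
#' b_{km'}}. Block averaging amplifies small systematic per-sample shifts
#' relative to per-gene noise: smooth trends in the sorted centered profile
#' reveal expression-level-dependent bias, while constant offsets in the
#' random-order profile reveal residual normalization shifts.
#'
#' @param m A log2-offset-scale `ExpressionMatrix`.
#' @param block_size Genes per block, `B >= 1`, `B <= N`.
#' @param ordering `"sorted_by_mean"` (default) or `"random"`.
#' @param seed Required when `ordering = "random"`.
#' @return A `BlockProfile`: list with `block_size`, `n_blocks`, `ordering`,
#'   `block_means_expression` (per-block mean of \eqn{\bar g_n}), `raw`
#'   (K x M matrix) and `centered` (K x M).
#' @export
block_profile <- function(m, block_size,
                          ordering = c("sorted_by_mean", "random"),
                          seed = NULL) {
  .assert_em(m, "log2_offset")
  ordering <- match.arg(ordering)
  N <- nrow(m$values)
  if (block_size < 1L) stop("'block_size' must be >= 1")
  if (block_size > N) stop("'block_size' exceeds the number of genes")
  K <- as.integer(N %/% block_size)
  ord <- if (ordering == "sorted_by_mean") {
    .mean_order(m)
  } else {
    if (is.null(seed)) stop("'seed' is required for random ordering")
    set.seed(seed)
    sample.int(N)
  }
  idx <- ord[seq_len(K * block_size)]
  f <- rep(seq_len(K), each = block_size)
  raw <- rowsum(m$values[idx, , drop = FALSE], f, reorder = FALSE) / block_size
  means <- rowMeans(m$values)
  bme <- as.numeric(rowsum(means[idx], f, reorder = FALSE)) / block_size
  centered <- raw - rowMeans(raw)
  dimnames(raw) <- dimnames(centered) <- list(NULL, sample_ids(m))
  structure(list(block_size = block_size, n_blocks = K, ordering = ordering,
                 block_means_expression = bme, raw = raw, centered = centered),
            class = "BlockProfile")
}

#' @export
print.BlockProfile <- function(x, ...) {
  cat(sprintf("BlockProfile: %d blocks of %d genes (%s order), %d samples\n",
              x$n_blocks, x$block_size, x$ordering, ncol(x$raw)))
  invisible(x)
}

#' Variance (or sd) versus mean expression profile
#'
#' Per-gene across-sample standard deviations (or variances, unbiased M-1
#' denominator) averaged over windows of genes sorted by mean expression.
#' A flat profile indicates that across-sample variability is independent of
#' expression level. By default windows are non-overlapping and tile the
#' sorted order (trailing remainder dropped); `moving = TRUE` instead returns
#' a centered moving average over the sorted per-gene values.
#'
#' @param m A log2-offset-scale `ExpressionMatrix` with at least 2 samples.
#' @param window Genes per window (default 800); must satisfy
#'   `2 <= window <= N`.
#' @param stat `"sd"` (default) or `"var"`.
#' @param moving Use a centered moving average instead of tiling windows.
#' @return A `VarianceProfile`: list with `window`, `stat`, `moving`,
#'   `mean_grid` (mean expression per window / position) and `avg` (windowed
#'   average of the per-gene statistic).
#' @export
variance_profile <- function(m, window = 800, stat = c("sd", "var"),
                             moving = FALSE) {
  .assert_em(m, "log2_offset")
  stat <- match.arg(stat)
  N <- nrow(m$values); M <- ncol(m$values)
  if (M < 2L) stop("variance profile needs at least 2 samples")
  if (window < 2L) stop("'window' must be >= 2")
  if (window > N) stop("'window' exceeds the number of genes")
  means <- rowMeans(m$values)
  v <- rowSums((m$values - means)^2) / (M - 1)
  s <- if (stat == "sd") sqrt(v) else v
  ord <- .mean_order(m)
  ms <- means[ord]; ss <- s[ord]
  if (moving) {
    kern <- rep(1 / window, window)
    avg <- as.numeric(stats::filter(ss, kern, sides = 2))
    keep <- !is.na(avg)
    grid <- ms[keep]; avg <- avg[keep]
  } else {
    W <- N %/% window
    idx <- seq_len(W * window)
    f <- rep(seq_len(W), each = window)
    grid <- as.numeric(rowsum(ms[idx], f)) / window
    avg <- as.numeric(rowsum(ss[idx], f)) / window
  }
  structure(list(window = window, stat = stat, moving = moving,
                 mean_grid = grid, avg = avg),
            class = "VarianceProfile")
}

# D'Agostino-Belanger-D'Agostino (1990) omnibus K^2 normality statistic,
# vectorized over the rows of a matrix of observations. Requires n >= 8.
.dagostino_rows <- function(x) {
  n <- ncol(x)
  if (n < 8L) stop("d'Agostino omnibus test requires at least 8 observations")
  mu <- rowMeans(x)
  d <- x - mu
  m2 <- rowMeans(d^2)
  m3 <- rowMeans(d^3)
  m4 <- rowMeans(d^4)
  b1 <- m3 / m2^1.5
  # skewness component
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * asinh(y / alpha)
  # kurtosis component
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term2 <- sign(denom) * (abs((1 - 2 / A) / denom))^(1 / 3)
  term2[denom == 0] <- Inf
  Z2 <- ((1 - 2 / (9 * A)) - term2) / sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  list(statistic = K2, p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

#' D'Agostino omnibus normality test
#'
#' The K-squared omnibus test combining transformed sample skewness and
#' kurtosis; the statistic is approximately chi-squared with 2 degrees of
#' freedom under normality. Requires at least 8 observations (20 or more is
#' recommended for the kurtosis approximation).
#'
#' @param x Numeric vector of observations.
#' @return List with `statistic` (K-squared) and `p.value`.
#' @export
dagostino_test <- function(x) {
  x <- as.numeric(x)
  res <- .dagostino_rows(matrix(x, nrow = 1L))
  list(statistic = as.numeric(res$statistic), p.value = as.numeric(res$p.value))
}

#' Per-gene normality sweep
#'
#' Applies the d'Agostino omnibus test to each gene's values across samples
#' and returns the sorted p-value curve, for plotting against uniform
#' quantiles (a curve on the 0-1 diagonal is consistent with normality). With
#' `group_size > 1`, samples are first randomly partitioned into
#' `floor(M/group_size)` disjoint groups and per-gene group means replace the
#' per-sample values, probing the central-limit behaviour of subpopulation
#' averages (e.g. 16-patient averages).
#'
#' @param m A log2-offset-scale `ExpressionMatrix`.
#' @param group_size Samples per group (default 1 = no grouping).
#' @param seed Required when `group_size > 1` (random partition).
#' @return Numeric vector of per-gene p-values, sorted ascending.
#' @export
normality_sweep <- function(m, group_size = 1L, seed = NULL) {
  .assert_em(m, "log2_offset")
  M <- ncol(m$values)
  if (group_size < 1L) stop("'group_size' must be >= 1")
  n_obs <- M %/% group_size
  if (n_obs < 8L)
    stop(sprintf("floor(M/group_size) = %d observations; at least 8 are required",
                 n_obs))
  x <- if (group_size == 1L) {
    m$values
  } else {
    if (is.null(seed)) stop("'seed' is required when group_size > 1")
    set.seed(seed)
    perm <- sample.int(M)[seq_len(n_obs * group_size)]
    f <- rep(seq_len(n_obs), each = group_size)
    # per-gene group means: genes x n_obs
    t(rowsum(t(m$values[, perm, drop = FALSE]), f, reorder = FALSE)) / group_size
  }
  sort(.dagostino_rows(x)$p.value)
}
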