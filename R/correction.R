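#' @name correction
#' @title Per-sample bias corrections
#'
#' @description Three corrections of increasing expressiveness, all defined on
#' the log2 scale:
#'
#' * **shift**: subtracts each sample's mean deviation from the consensus
#'   profile (equivalent to a per-sample multiplicative renormalization on the
#'   raw scale). Removes constant offsets only.
#' * **LLT** (local-leveling transform): models each sample's bias as a
#'   polynomial \eqn{\beta_m(\bar g_n)} in the gene's across-sample mean
#'   expression, fitted by weighted least squares on block-averaged deviations,
#'   and subtracts it.
#' * **NLT** (nonlinear transform): models a per-sample nonlinear change of
#'   scale \eqn{G_{nm} = \alpha_m(g_{nm}) + \epsilon_{nm}} with
#'   \eqn{\alpha_m(g) = \sum_\ell a_{m\ell}\, g^\ell}, fitted by unweighted
#'   least squares of block-averaged gene means on block averages of the
#'   sample's own value powers, and evaluates \eqn{\hat\alpha_m} at each
#'   measured value.
#'
#' Block averaging over `span` consecutive genes in mean-expression-sorted
#' order suppresses per-gene noise so the smooth per-sample bias becomes
#' estimable by low-order polynomial regression.
NULL

# ---- polynomial helpers -----------------------------------------------------

# coefficient-vector product of two polynomials (ascending powers)
.polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# Horner evaluation of polynomial with ascending coefficients
.polyeval <- function(coef, x) {
  out <- rep(coef[length(coef)], length(x))
  for (l in rev(seq_len(length(coef) - 1L))) out <- out * x + coef[l]
  out
}

# Rebase a polynomial in u = (x - mu)/s to ascending coefficients in x
.rebase_poly <- function(coef_u, mu, s) {
  L <- length(coef_u) - 1L
  acc <- numeric(L + 1L)
  basis <- c(-mu / s, 1 / s)     # u as a polynomial in x
  pw <- 1                        # u^0
  for (l in 0:L) {
    acc[seq_along(pw)] <- acc[seq_along(pw)] + coef_u[l + 1L] * pw
    if (l < L) pw <- .polymul(pw, basis)
  }
  acc
}

# ---- model container --------------------------------------------------------

.patient_bias_model <- function(kind, order, coefficients, fit_block_size,
                                weighted, residual_mse, fitted_on_means) {
  if (any(!is.finite(coefficients))) stop("non-finite model coefficients")
  structure(list(kind = kind, order = order, coefficients = coefficients,
                 fit_block_size = fit_block_size, weighted = weighted,
                 residual_mse = residual_mse,
                 fitted_on_means = fitted_on_means),
            class = "PatientBiasModel")
}

#' @export
print.PatientBiasModel <- function(x, ...) {
  cat(sprintf("PatientBiasModel: kind=%s, order=%d, %d samples%s\n",
              x$kind, x$order, nrow(x$coefficients),
              if (!is.na(x$fit_block_size))
                sprintf(", fit span K=%d", x$fit_block_size) else ""))
  invisible(x)
}

.check_gene_set <- function(m, model) {
  if (is.null(model$fitted_on_means)) return(invisible(NULL))
  if (!setequal(gene_ids(m), names(model$fitted_on_means)))
    stop("gene set of the matrix does not match the gene set the model was fitted on")
  invisible(NULL)
}

# sorted-block fitting design shared by LLT and NLT: mean-sorted gene order,
# floor(N/K) full blocks, remainder dropped
.fit_blocks <- function(m, K) {
  N <- nrow(m$values)
  nb <- N %/% K
  ord <- .mean_order(m)
  list(idx = ord[seq_len(nb * K)], f = rep(seq_len(nb), each = K), nb = nb)
}

# ---- shift ------------------------------------------------------------------

#' Per-sample shift correction
#'
#' Subtracts from each sample's column its mean deviation
#' \eqn{s_m = \frac1N \sum_n (g_{nm} - \bar g_n)}, an additive log-space shift
#' equivalent to a multiplicative renormalization on the raw scale. After
#' correction every sample's mean deviation is exactly zero, so unsorted block
#' profiles coincide; expression-level-dependent trends are untouched.
#'
#' @param m A log2-offset-scale `ExpressionMatrix`.
#' @return List with `matrix` (corrected `ExpressionMatrix`) and `model`
#'   (a `kind = "shift"` `PatientBiasModel` holding the subtracted shifts).
#' @export
shift_correct <- function(m) {
  .assert_em(m, "log2_offset")
  shifts <- colMeans(m$values) - mean(rowMeans(m$values))
  corrected <- expression_matrix(sweep(m$values, 2L, shifts, "-"),
                                 gene_ids(m), sample_ids(m),
                                 scale = m$scale, offset_c = m$offset_c)
  coefs <- matrix(shifts, ncol = 1L,
                  dimnames = list(sample_ids(m), "c0"))
  model <- .patient_bias_model("shift", 0L, coefs, NA_integer_, FALSE,
                               stats::setNames(rep(NA_real_, ncol(m$values)),
                                               sample_ids(m)),
                               NULL)
  list(matrix = corrected, model = model)
}

# ---- LLT --------------------------------------------------------------------

#' Fit the local-leveling transform
#'
#' For each sample m, regresses block-averaged deviations
#' \eqn{\langle g_{nm} - \bar g_n \rangle_K} on a degree-`degree` polynomial in
#' the block-averaged mean expression \eqn{\langle \bar g_n \rangle_K}, with
#' per-block weights \eqn{w_k = 1/\max(\langle \mathrm{Var}_m(g_{nm})
#' \rangle_K, 10^{-8})} (inverse block-averaged across-sample variance; the
#' between-sample variation of expression is the dominant error source).
#' Predictors are centered and scaled internally for conditioning; returned
#' coefficients are on the original basis.
#'
#' @param m A log2-offset-scale `ExpressionMatrix` with at least 2 samples.
#' @param degree Polynomial degree L (default 3).
#' @param span Block-averaging span K in genes (default 50).
#' @param weighted Use inverse-variance weights (default `TRUE`).
#' @return A `kind = "llt"` `PatientBiasModel` with an M x (L+1) coefficient
#'   matrix, per-sample residual MSE, and the \eqn{\bar g_n} snapshot used in
#'   fitting (needed by [apply_llt()]).
#' @export
fit_llt <- function(m, degree = 3L, span = 50L, weighted = TRUE) {
  .assert_em(m, "log2_offset")
  M <- ncol(m$values)
  if (M < 2L) stop("fitting requires at least 2 samples")
  if (degree < 0L) stop("'degree' must be >= 0")
  bl <- .fit_blocks(m, span)
  if (bl$nb < degree + 2L)
    stop(sprintf("only %d blocks of span %d available; need at least degree + 2 = %d",
                 bl$nb, span, degree + 2L))
  gbar <- rowMeans(m$values)
  dev <- m$values - gbar
  x <- as.numeric(rowsum(gbar[bl$idx], bl$f)) / span
  Y <- rowsum(dev[bl$idx, , drop = FALSE], bl$f) / span
  w <- if (weighted) {
    vg <- rowSums(dev^2) / (M - 1)
    1 / pmax(as.numeric(rowsum(vg[bl$idx], bl$f)) / span, 1e-8)
  } else rep(1, bl$nb)
  mu <- mean(x); s <- stats::sd(x)
  Z <- outer((x - mu) / s, 0:degree, `^`)
  fit <- stats::lm.wfit(Z, Y, w)
  cz <- as.matrix(fit$coefficients)
  if (anyNA(cz)) {
    bad <- sample_ids(m)[colSums(is.na(cz)) > 0][1]
    stop("singular local-leveling design for sample '", bad, "'")
  }
  coefs <- t(apply(cz, 2L, .rebase_poly, mu = mu, s = s))
  dimnames(coefs) <- list(sample_ids(m), paste0("c", 0:degree))
  mse <- colMeans(as.matrix(fit$residuals)^2)
  names(mse) <- sample_ids(m)
  .patient_bias_model("llt", as.integer(degree), coefs, as.integer(span),
                      weighted, mse, gbar)
}

#' Apply the local-leveling transform
#'
#' \eqn{\hat G_{nm} = g_{nm} - \sum_\ell \hat b_{m\ell}\, \bar g_n^\ell},
#' evaluating each sample's bias polynomial at the \eqn{\bar g_n} snapshot
#' stored at fitting time (fit and apply form a consistent pair; applying a
#' model to a different gene set is refused).
#'
#' @param m A log2-offset-scale `ExpressionMatrix` with the same gene set the
#'   model was fitted on.
#' @param model A `kind = "llt"` `PatientBiasModel` from [fit_llt()].
#' @return The corrected `ExpressionMatrix`.
#' @export
apply_llt <- function(m, model) {
  .assert_em(m, "log2_offset")
  if (!inherits(model, "PatientBiasModel") || model$kind != "llt")
    stop("'model' must be a PatientBiasModel of kind 'llt'")
  .check_gene_set(m, model)
  if (!setequal(sample_ids(m), rownames(model$coefficients)))
    stop("sample set of the matrix does not match the model")
  gbar <- model$fitted_on_means[gene_ids(m)]
  V <- outer(gbar, 0:model$order, `^`)           # N x (L+1)
  bias <- V %*% t(model$coefficients[sample_ids(m), , drop = FALSE])
  expression_matrix(m$values - bias, gene_ids(m), sample_ids(m),
                    scale = m$scale, offset_c = m$offset_c)
}

# ---- NLT --------------------------------------------------------------------

#' Fit the nonlinear (scale-distortion) transform
#'
#' For each sample m, ordinary least squares of the block-averaged consensus
#' \eqn{\langle \bar g_n \rangle_K} on the block averages of the sample's own
#' value powers \eqn{\langle g_{nm}^\ell \rangle_K}, \eqn{\ell = 0..L}. Note
#' the predictors are block averages *of powers*, not powers of block
#' averages. The combined residual has no clear relation to expression level,
#' hence unweighted regression. Predictor columns are standardized internally
#' and coefficients mapped back to the raw power basis.
#'
#' @inheritParams fit_llt
#' @return A `kind = "nlt"` `PatientBiasModel` with the estimated
#'   \eqn{\hat a_{m\ell}} per sample.
#' @export
fit_nlt <- function(m, degree = 3L, span = 50L) {
  .assert_em(m, "log2_offset")
  M <- ncol(m$values)
  if (M < 2L) stop("fitting requires at least 2 samples")
  if (degree < 1L) stop("'degree' must be >= 1")
  bl <- .fit_blocks(m, span)
  if (bl$nb < degree + 2L)
    stop(sprintf("only %d blocks of span %d available; need at least degree + 2 = %d",
                 bl$nb, span, degree + 2L))
  gbar <- rowMeans(m$values)
  y <- as.numeric(rowsum(gbar[bl$idx], bl$f)) / span
  # block averages of per-sample powers, one K x M matrix per power
  pw <- lapply(0:degree, function(l)
    rowsum(m$values[bl$idx, , drop = FALSE]^l, bl$f) / span)
  coefs <- matrix(NA_real_, M, degree + 1L,
                  dimnames = list(sample_ids(m), paste0("c", 0:degree)))
  mse <- stats::setNames(numeric(M), sample_ids(m))
  for (j in seq_len(M)) {
    X <- vapply(pw, function(p) p[, j], numeric(bl$nb))   # nb x (L+1)
    mu <- colMeans(X[, -1L, drop = FALSE])
    sdev <- apply(X[, -1L, drop = FALSE], 2L, stats::sd)
    if (any(sdev == 0)) stop("singular nonlinear-transform design for sample '",
                             sample_ids(m)[j], "'")
    Xs <- cbind(1, sweep(sweep(X[, -1L, drop = FALSE], 2L, mu, "-"),
                         2L, sdev, "/"))
    fit <- stats::lm.fit(Xs, y)
    b <- fit$coefficients
    if (anyNA(b)) stop("singular nonlinear-transform design for sample '",
                       sample_ids(m)[j], "'")
    a <- numeric(degree + 1L)
    a[-1L] <- b[-1L] / sdev
    a[1L] <- b[1L] - sum(b[-1L] * mu / sdev)
    coefs[j, ] <- a
    mse[j] <- mean(fit$residuals^2)
  }
  .patient_bias_model("nlt", as.integer(degree), coefs, as.integer(span),
                      FALSE, mse, gbar)
}

#' Apply the nonlinear transform
#'
#' \eqn{\hat G_{nm} = \sum_\ell \hat a_{m\ell}\, g_{nm}^\ell}, evaluated
#' entrywise at each sample's own measured values, over the full observed
#' range (no monotonicity constraint is imposed; a warning is issued if any
#' sample's fitted \eqn{\hat\alpha_m} is non-monotone on its observed range).
#'
#' @param m A log2-offset-scale `ExpressionMatrix` with the same gene set the
#'   model was fitted on.
#' @param model A `kind = "nlt"` `PatientBiasModel` from [fit_nlt()].
#' @return The corrected `ExpressionMatrix`.
#' @export
apply_nlt <- function(m, model) {
  .assert_em(m, "log2_offset")
  if (!inherits(model, "PatientBiasModel") || model$kind != "nlt")
    stop("'model' must be a PatientBiasModel of kind 'nlt'")
  .check_gene_set(m, model)
  if (!setequal(sample_ids(m), rownames(model$coefficients)))
    stop("sample set of the matrix does not match the model")
  out <- m$values
  n_nonmono <- 0L
  for (j in seq_len(ncol(out))) {
    a <- model$coefficients[sample_ids(m)[j], ]
    g <- m$values[, j]
    out[, j] <- .polyeval(a, g)
    grid <- seq(min(g), max(g), length.out = 201L)
    if (any(diff(.polyeval(a, grid)) < 0)) n_nonmono <- n_nonmono + 1L
  }
  if (n_nonmono > 0L)
    warning(sprintf("fitted nonlinear transform is non-monotone on the observed range for %d sample(s)",
                    n_nonmono))
  expression_matrix(out, gene_ids(m), sample_ids(m),
                    scale = m$scale, offset_c = m$offset_c)
}

#' Per-sample distortion curves
#'
#' Evaluates each sample's fitted transform on an expression-level grid for
#' plotting. For an NLT model the curve is \eqn{\hat\alpha_m(g)}; for an LLT
#' model it is \eqn{g - \hat\beta_m(g)} (the corrected value as a function of
#' the mean level). The `deviation` column is the curve minus the identity.
#'
#' @param model A `PatientBiasModel` of kind `"llt"` or `"nlt"`.
#' @param grid Non-empty numeric vector of log2 expression levels.
#' @return A data frame with columns `sample_id`, `g`, `curve`, `deviation`.
#' @export
distortion_curves <- function(model, grid) {
  if (!inherits(model, "PatientBiasModel") || !model$kind %in% c("llt", "nlt"))
    stop("'model' must be a PatientBiasModel of kind 'llt' or 'nlt'")
  if (length(grid) == 0L) stop("'grid' must be non-empty")
  ids <- rownames(model$coefficients)
  res <- lapply(ids, function(id) {
    cf <- model$coefficients[id, ]
    curve <- if (model$kind == "nlt") .polyeval(cf, grid)
             else grid - .polyeval(cf, grid)
    data.frame(sample_id = id, g = grid, curve = curve,
               deviation = curve - grid, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
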