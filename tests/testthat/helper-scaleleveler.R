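# shared fixture builders (all data generated in code)

# quick log2-scale matrix from a numeric matrix
log_em <- function(values, offset_c = 0.25) {
  expression_matrix(values,
                    gene_ids = sprintf("g%04d", seq_len(nrow(values))),
                    sample_ids = sprintf("s%03d", seq_len(ncol(values))),
                    scale = "log2_offset", offset_c = offset_c)
}

# random log2-scale matrix with distinct gene means
random_log_em <- function(n_genes, n_samples, seed, sd = 0.5,
                          mean_range = c(3, 12)) {
  set.seed(seed)
  mu <- seq(mean_range[1], mean_range[2], length.out = n_genes)
  log_em(mu + matrix(rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples))
}

# TPR of the mean ROC curve at a single FPR value
mean_tpr_at <- function(ens, fpr) {
  ens$mean_curve[which.min(abs(ens$grid - fpr))]
}
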