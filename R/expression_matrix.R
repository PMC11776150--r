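#' Construct an expression matrix
#'
#' The central container of the package: a genes x samples matrix of expression
#' values together with its scale state. Values are either on the raw scale
#' (non-negative counts, TPM or FPKM) or on the offset-log scale
#' \eqn{\log_2(x + c)}, with the offset \eqn{c} recorded so that transforms can
#' be reasoned about (and inverted) downstream.
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids Character vector of unique sample identifiers (defaults to
#'   `colnames(values)`).
#' @param scale Either `"raw"` or `"log2_offset"`.
#' @param offset_c Non-negative offset used in the log transform; only
#'   meaningful when `scale = "log2_offset"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the dimnamed matrix), `scale` and `offset_c`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2), paste0("g", 1:3), c("s1", "s2"))
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale = c("raw", "log2_offset"),
                              offset_c = NA_real_) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least one gene and one sample")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("length of 'gene_ids' does not match number of rows")
  if (length(sample_ids) != ncol(values))
    stop("length of 'sample_ids' does not match number of columns")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids: ",
    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids: ",
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (scale == "raw" && any(values < 0))
    stop("raw-scale expression values must be non-negative")
  if (scale == "log2_offset") {
    if (is.na(offset_c) || offset_c < 0)
      stop("'offset_c' must be a non-negative real when scale is 'log2_offset'")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, scale = scale, offset_c = offset_c),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s%s]\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (x$scale == "log2_offset") sprintf(", c=%g", x$offset_c) else ""))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers
#' @param m An `ExpressionMatrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(m) colnames(m$values)

.assert_em <- function(m, scale = NULL) {
  if (!inherits(m, "ExpressionMatrix")) stop("expected an ExpressionMatrix")
  if (!is.null(scale) && m$scale != scale)
    stop(sprintf("expected a matrix on the '%s' scale, got '%s'", scale, m$scale))
  invisible(m)
}

#' Read an expression matrix from delimited text
#'
#' Reads a TSV or CSV table (delimiter auto-detected from the file extension:
#' `.csv` means comma, anything else tab) with one header row and one leading
#' id column. A leading comment line of the form
#' `# scale=log2_offset offset_c=0.25` (written by [write_expression_matrix()])
#' restores the scale metadata; without it the matrix is assumed raw.
#'
#' @param path Path to the file.
#' @param genes_in `"rows"` if genes are rows on disk (canonical), `"columns"`
#'   if the table is transposed.
#' @return An [expression_matrix()] in genes x samples orientation.
#' @export
read_expression_matrix <- function(path, genes_in = c("rows", "columns")) {
  genes_in <- match.arg(genes_in)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  scale <- "raw"
  offset_c <- NA_real_
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    if (grepl("scale=log2_offset", first)) scale <- "log2_offset"
    cm <- regmatches(first, regexec("offset_c=([0-9.eE+-]+)", first))[[1]]
    if (length(cm) == 2L) offset_c <- as.numeric(cm[2])
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"")
  if (ncol(tab) < 2L) stop("expected an id column plus at least one data column in ", path)
  ids <- tab[[1L]]
  header_ids <- colnames(tab)[-1L]
  vals <- matrix(NA_real_, nrow(tab), ncol(tab) - 1L)
  for (j in seq_len(ncol(tab) - 1L)) {
    col <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row id '%s', column '%s' in %s",
                   col[bad[1]], ids[bad[1]], header_ids[j], path))
    vals[, j] <- num
  }
  if (genes_in == "rows") {
    expression_matrix(vals, gene_ids = ids, sample_ids = header_ids,
                      scale = scale, offset_c = offset_c)
  } else {
    expression_matrix(t(vals), gene_ids = header_ids, sample_ids = ids,
                      scale = scale, offset_c = offset_c)
  }
}

#' Write an expression matrix to delimited text
#'
#' Writes genes x samples (canonical orientation), first column `gene_id`,
#' header row of sample ids, preceded by a `#` comment line carrying the scale
#' metadata. Values are printed with 17 significant digits so that
#' [read_expression_matrix()] reproduces them exactly.
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output path; `.csv` writes comma-separated, otherwise tab.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(m, path) {
  .assert_em(m)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  meta <- if (m$scale == "log2_offset")
    sprintf("# scale=log2_offset offset_c=%.17g", m$offset_c)
  else "# scale=raw"
  header <- paste(c("gene_id", sample_ids(m)), collapse = sep)
  body <- paste(gene_ids(m),
                apply(m$values, 1L, function(r)
                  paste(sprintf("%.17g", r), collapse = sep)),
                sep = sep)
  ok <- tryCatch({
    writeLines(c(meta, header, body), con = path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write expression matrix to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Offset log2 transform
#'
#' Applies \eqn{x \mapsto \log_2(x + c)} entrywise. The offset \eqn{c} keeps
#' unexpressed genes (\eqn{x = 0}) finite. The default \eqn{c = 0.25} is the
#' mean of values that round to zero when small true values are approximately
#' uniform on \[0, 0.5).
#'
#' @param m A raw-scale `ExpressionMatrix`.
#' @param c Non-negative offset (default 0.25).
#' @return A log2-offset-scale `ExpressionMatrix` of the same shape and ids.
#' @export
log_transform <- function(m, c = 0.25) {
  .assert_em(m, "raw")
  if (!is.numeric(c) || length(c) != 1L || c < 0)
    stop("'c' must be a single non-negative real")
  if (c == 0 && any(m$values == 0))
    stop("c = 0 with zero entries would transform to -Inf; use a positive offset")
  expression_matrix(log2(m$values + c), gene_ids(m), sample_ids(m),
                    scale = "log2_offset", offset_c = c)
}

#' First-order offset distortion bound
#'
#' For a gene with true raw expression `X`, multiplicative measurement bias `b`
#' and log offset `c`, the offset inflates the measured raw value by a factor
#' `1 + c/(bX)`. This returns the first-order term `c/(bX)`, the fractional
#' distortion introduced by the offset. At `X = 8`, `b = 1`, `c = 0.25` it is
#' 1/32, about 3 percent -- the rationale for filtering to genes with mean raw
#' expression above 8 (log2 mean above 3).
#'
#' @param X True raw expression level(s), positive.
#' @param b Multiplicative bias, positive.
#' @param c Non-negative offset.
#' @return `c / (b * X)`, vectorized over the inputs.
#' @export
offset_distortion_bound <- function(X, b = 1, c = 0.25) {
  if (any(X <= 0)) stop("'X' must be positive")
  if (any(b <= 0)) stop("'b' must be positive")
  if (any(c < 0)) stop("'c' must be non-negative")
  c / (b * X)
}

#' Filter genes by mean log2 expression
#'
#' Retains exactly the genes whose across-sample mean log2 expression strictly
#' exceeds `threshold`. Filtering is defined on the log scale (default
#' threshold 3, i.e. raw mean above 8) and is applied once, after the log
#' transform and before any correction.
#'
#' @param m A log2-offset-scale `ExpressionMatrix`.
#' @param threshold Log2-scale threshold (default 3).
#' @return A list with elements `matrix` (the filtered `ExpressionMatrix`) and
#'   `report`, a `FilterReport` list with `retained_gene_ids`,
#'   `dropped_gene_ids`, `threshold` and `n_retained`.
#' @export
filter_by_mean_expression <- function(m, threshold = 3.0) {
  .assert_em(m, "log2_offset")
  means <- rowMeans(m$values)
  keep <- means > threshold
  if (!any(keep))
    stop(sprintf(
      "all %d genes fall at or below the mean-expression threshold %g; try a lower threshold",
      length(keep), threshold))
  report <- structure(list(retained_gene_ids = gene_ids(m)[keep],
                           dropped_gene_ids = gene_ids(m)[!keep],
                           threshold = threshold,
                           n_retained = sum(keep)),
                      class = "FilterReport")
  filtered <- expression_matrix(m$values[keep, , drop = FALSE],
                                gene_ids(m)[keep], sample_ids(m),
                                scale = m$scale, offset_c = m$offset_c)
  list(matrix = filtered, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport: %d genes retained, %d dropped (mean log2 threshold %g)\n",
              x$n_retained, length(x$dropped_gene_ids), x$threshold))
  invisible(x)
}
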