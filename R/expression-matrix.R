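#' Expression matrix container
#'
#' A light container for a genes x samples expression matrix with an explicit
#' scale tag. `"linear"` matrices must be complete and non-negative (RSEM/FPKM
#' style values); `"log2p1"` marks matrices produced by [log_transform()].
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs).
#' @param scale `"linear"` or `"log2p1"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `scale`.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_ptc("ptc_validation", "expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_ptc("ptc_validation", "expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_ptc("ptc_validation", "duplicate gene_ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop_ptc("ptc_validation", "duplicate sample_ids in expression matrix")
  if (anyNA(values))
    stop_ptc("ptc_validation", "expression matrix contains missing values")
  if (scale == "linear" && any(values < 0))
    stop_ptc("ptc_validation", "linear-scale expression must be non-negative")
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (scale=%s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @rdname expression_matrix
#' @param E an `ExpressionMatrix`.
#' @export
gene_ids <- function(E) rownames(E$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(E) colnames(E$values)

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

as_expression <- function(E) {
  if (inherits(E, "ExpressionMatrix")) return(E)
  stop_ptc("ptc_validation", "expected an ExpressionMatrix")
}

#' Read a gene-by-sample expression TSV
#'
#' Expects a header row (`gene_id` then sample IDs) and one numeric row per
#' gene. Duplicate gene rows are collapsed by their mean (in linear space).
#'
#' @param path path to a tab-delimited file.
#' @return `ExpressionMatrix` with `scale = "linear"`.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path))
    stop_ptc("ptc_io", "expression file not found: %s", path)
  raw <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "character"),
    error = function(e)
      stop_ptc("ptc_format", "cannot parse expression TSV '%s': %s", path,
               conditionMessage(e)))
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop_ptc("ptc_format", "empty or malformed expression TSV: %s", path)
  genes <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = dimnames(body)))
  bad <- which(is.na(num) , arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_ptc("ptc_parse",
             "non-numeric expression value '%s' at gene '%s', sample '%s'",
             body[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
             colnames(body)[bad[1, 2]])
  }
  if (any(num < 0)) {
    neg <- which(num < 0, arr.ind = TRUE)
    stop_ptc("ptc_validation",
             "negative expression value at gene '%s', sample '%s'",
             genes[neg[1, 1]], colnames(num)[neg[1, 2]])
  }
  n_in <- length(genes)
  if (anyDuplicated(genes)) {
    # collapse duplicates by mean, keeping first-appearance order
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(num) <- genes
  ptc_log("read_expression_tsv: %d rows -> %d genes, %d samples (%d duplicates collapsed)",
          n_in, nrow(num), ncol(num), n_in - nrow(num))
  expression_matrix(num, "linear")
}

#' Write an expression matrix as TSV
#'
#' @param E `ExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(E, path) {
  E <- as_expression(E)
  df <- data.frame(gene_id = gene_ids(E), E$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-transform a linear expression matrix
#'
#' Applies `log2(x + pseudocount)` elementwise, the conventional transform for
#' RSEM/FPKM-style values before factorization.
#'
#' @param E linear-scale `ExpressionMatrix`.
#' @param pseudocount positive offset (default 1).
#' @return `ExpressionMatrix` with `scale = "log2p1"`.
#' @export
log_transform <- function(E, pseudocount = 1) {
  E <- as_expression(E)
  if (E$scale != "linear")
    stop_ptc("ptc_state", "log_transform: matrix is already log-scale")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop_ptc("ptc_validation", "pseudocount must be a positive scalar")
  out <- log2(E$values + pseudocount)
  structure(list(values = out, scale = "log2p1"), class = "ExpressionMatrix")
}

#' Keep the most variable genes
#'
#' Ranks genes by median absolute deviation (MAD) across samples and keeps the
#' top `n`; ties are broken by lexicographic gene ID so the selection is
#' deterministic.
#'
#' @param E `ExpressionMatrix`.
#' @param n number of genes to keep.
#' @return `ExpressionMatrix` restricted to the selected genes (original row
#'   order within the selection is by decreasing MAD).
#' @export
select_variable_genes <- function(E, n) {
  E <- as_expression(E)
  if (n > nrow(E$values) || n < 1L)
    stop_ptc("ptc_bounds", "n=%d out of range for %d genes", n, nrow(E$values))
  mads <- apply(E$values, 1L, mad)
  ord <- order(-mads, rownames(E$values), method = "radix")
  keep <- ord[seq_len(n)]
  structure(list(values = E$values[keep, , drop = FALSE], scale = E$scale),
            class = "ExpressionMatrix")
}

#' Align an expression matrix to a reference gene list
#'
#' Subsets and reorders rows to the intersection with `reference_gene_ids`, in
#' reference order. Dropped reference genes are reported via the
#' `"dropped"` attribute.
#'
#' @param E `ExpressionMatrix`.
#' @param reference_gene_ids character vector of gene IDs.
#' @return `ExpressionMatrix` with attribute `dropped` (reference genes absent
#'   from `E`).
#' @export
align_genes <- function(E, reference_gene_ids) {
  E <- as_expression(E)
  shared <- reference_gene_ids[reference_gene_ids %in% gene_ids(E)]
  if (length(shared) == 0L)
    stop_ptc("ptc_alignment", "no genes shared with the reference list")
  dropped <- setdiff(reference_gene_ids, shared)
  ptc_log("align_genes: %d shared, %d reference genes dropped",
          length(shared), length(dropped))
  out <- structure(list(values = E$values[shared, , drop = FALSE],
                        scale = E$scale), class = "ExpressionMatrix")
  attr(out, "dropped") <- dropped
  out
}
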