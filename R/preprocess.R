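#' Remove genes detected in too few cells
#'
#' A gene counts as "expressed" in a cell when its entry is strictly
#' positive. Genes expressed in fewer than `min_fraction` of cells are
#' dropped; the boundary fraction is kept (`>=`). Gene order is preserved.
#'
#' @param X An [expression_matrix()] of raw or library-normalized counts.
#' @param min_fraction Minimum fraction of cells, in (0, 1). The reference
#'   protocol uses 0.10 for benchmark single-cell data and 0.05 for PBMC.
#' @return A filtered `expr_matrix`.
#' @export
filter_genes_by_cell_fraction <- function(X, min_fraction = 0.1) {
  stopifnot_counts(X, "filter_genes_by_cell_fraction")
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction >= 1)
    stop("min_fraction must lie in (0, 1)")
  frac <- rowMeans(X$values > 0)
  keep <- frac >= min_fraction
  if (!any(keep)) stop("all genes filtered: no gene is expressed in >= min_fraction of cells")
  expression_matrix(X$values[keep, , drop = FALSE])
}

#' Remove cells expressing too few genes
#'
#' @param X An [expression_matrix()] of counts.
#' @param min_genes Minimum number of genes with nonzero counts a cell must
#'   express to be retained (200 in the PBMC protocol).
#' @return A filtered `expr_matrix`.
#' @export
filter_cells_by_gene_count <- function(X, min_genes = 200) {
  stopifnot_counts(X, "filter_cells_by_gene_count")
  min_genes <- as.integer(min_genes)
  ngenes <- colSums(X$values > 0)
  keep <- ngenes >= min_genes
  if (!any(keep)) stop("all cells filtered: no cell expresses >= min_genes genes")
  expression_matrix(X$values[, keep, drop = FALSE])
}

#' Library-size normalization to a fixed total per cell
#'
#' Scales each cell (column) so its counts sum to `target_sum`
#' (10,000 by default, the usual CPM-like convention for single-cell data).
#'
#' @param X An [expression_matrix()] of counts.
#' @param target_sum Desired per-cell total.
#' @return A normalized `expr_matrix`.
#' @export
normalize_total_counts <- function(X, target_sum = 10000) {
  stopifnot_counts(X, "normalize_total_counts")
  cs <- colSums(X$values)
  if (any(cs == 0)) {
    bad <- colnames(X$values)[which(cs == 0)[1]]
    stop(sprintf("cell '%s' has zero total counts and cannot be normalized", bad))
  }
  expression_matrix(sweep(X$values, 2, target_sum / cs, `*`))
}

#' Select significantly variable genes
#'
#' Computes each gene's variance across cells and a per-gene p-value from a
#' chi-square test of that variance against the pooled median gene variance
#' under a Gaussian null (`df = m - 1`, upper tail). Genes are kept when the
#' Bonferroni-adjusted p-value falls below `alpha`. The test is a documented
#' stand-in: the reference preprocessing protocol computes variances and
#' p-values but does not restate the exact test; the QC report flags this.
#'
#' @param X An [expression_matrix()] (any normalization state).
#' @param alpha Significance level after Bonferroni correction (default 0.01).
#' @param null_variance Optional scalar null variance; defaults to the median
#'   per-gene variance.
#' @return A `gene_selection` list: `kept_gene_ids`, `per_gene_variance`,
#'   `per_gene_pvalue` (raw), `adjusted_pvalue`, `alpha`, `test`.
#' @export
select_variable_genes <- function(X, alpha = 0.01, null_variance = NULL) {
  if (!inherits(X, "expr_matrix")) stop("expected an 'expr_matrix' object")
  m <- n_cells(X)
  if (m < 2) stop("select_variable_genes() needs at least 2 cells")
  v <- apply(X$values, 1, stats::var)
  if (is.null(null_variance)) null_variance <- stats::median(v)
  if (null_variance <= 0 || all(v == v[1])) {
    p <- rep(1, length(v))
  } else {
    stat <- (m - 1) * v / null_variance
    p <- stats::pchisq(stat, df = m - 1, lower.tail = FALSE)
    p[v == 0] <- 1
  }
  padj <- pmin(1, p * length(p))
  keep <- padj < alpha
  structure(list(kept_gene_ids = gene_ids(X)[keep],
                 per_gene_variance = stats::setNames(v, gene_ids(X)),
                 per_gene_pvalue = stats::setNames(p, gene_ids(X)),
                 adjusted_pvalue = stats::setNames(padj, gene_ids(X)),
                 alpha = alpha,
                 test = "chi-square of gene variance vs pooled median variance (Gaussian null)"),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("<gene_selection> %d of %d genes kept (alpha = %g, Bonferroni)\n",
              length(x$kept_gene_ids), length(x$per_gene_variance), x$alpha))
  invisible(x)
}

#' Log-transform expression values
#'
#' Applies `log2(x + 1)` entry-wise and marks the matrix as log-transformed.
#' Applying it twice is an error.
#'
#' @param X An [expression_matrix()] with non-negative entries.
#' @return A log-transformed `expr_matrix`.
#' @export
log_transform <- function(X) {
  if (!inherits(X, "expr_matrix")) stop("expected an 'expr_matrix' object")
  if (X$is_log) stop("matrix is already log-transformed")
  out <- expression_matrix(log2(X$values + 1), is_log = TRUE)
  out$transform <- list(base = 2, pseudocount = 1)
  out
}

#' Keep the most variable genes
#'
#' Ranks genes by variance (descending, ties broken by gene id) and keeps the
#' union of `always_keep` and the top `k` remaining genes. `always_keep` is
#' how a user-supplied transcription-factor list is pinned into the matrix.
#'
#' @param X An [expression_matrix()].
#' @param k Number of top-variance genes to keep beyond `always_keep`.
#' @param always_keep Character vector of gene ids always retained.
#' @return An `expr_matrix` restricted to the selected genes, in original
#'   row order.
#' @export
top_k_by_variance <- function(X, k, always_keep = character()) {
  if (!inherits(X, "expr_matrix")) stop("expected an 'expr_matrix' object")
  ids <- gene_ids(X)
  unknown <- setdiff(always_keep, ids)
  if (length(unknown))
    stop("unknown gene_id in always_keep: ", paste(unknown, collapse = ", "))
  v <- apply(X$values, 1, stats::var)
  pool <- setdiff(ids, always_keep)
  if (k > length(pool)) stop("k exceeds the number of genes outside always_keep")
  ord <- pool[order(-v[pool], pool)]
  sel <- union(always_keep, ord[seq_len(k)])
  keep <- ids %in% sel
  expr <- expression_matrix(X$values[keep, , drop = FALSE],
                            is_log = X$is_log)
  expr$transform <- X$transform
  expr
}

#' Run the standard preprocessing chain with a QC report
#'
#' Convenience wrapper: gene fraction filter, optional cell filter, optional
#' total-count normalization, variance-based gene selection, log transform,
#' optional top-k restriction. Returns the processed matrix plus a QC report
#' (counts removed per step) suitable for JSON export.
#'
#' Denoising/imputation (e.g. diffusion-based smoothing of dropout) is out
#' of scope; a pre-imputed matrix produced by an external tool can simply be
#' supplied as `X` (via [read_expression()]) in place of raw counts.
#'
#' @param X Raw counts [expression_matrix()].
#' @param min_fraction,min_genes,target_sum,alpha,top_k,always_keep Stage
#'   parameters; a `NULL` value skips the stage (`alpha = NULL` skips the
#'   variance selection, `top_k = NULL` skips the top-k restriction).
#' @return List with `X` (processed) and `qc` (named list of stage records).
#' @export
preprocess_expression <- function(X, min_fraction = 0.1, min_genes = NULL,
                                  target_sum = NULL, alpha = 0.01,
                                  top_k = NULL, always_keep = character()) {
  qc <- list()
  n0 <- n_genes(X); m0 <- n_cells(X)
  if (!is.null(min_fraction)) {
    X <- filter_genes_by_cell_fraction(X, min_fraction)
    qc$gene_fraction_filter <- list(min_fraction = min_fraction,
                                    genes_removed = n0 - n_genes(X))
  }
  if (!is.null(min_genes)) {
    X <- filter_cells_by_gene_count(X, min_genes)
    qc$cell_gene_count_filter <- list(min_genes = min_genes,
                                      cells_removed = m0 - n_cells(X))
  }
  if (!is.null(target_sum)) {
    X <- normalize_total_counts(X, target_sum)
    qc$total_count_normalization <- list(target_sum = target_sum)
  }
  if (!is.null(alpha)) {
    sel <- select_variable_genes(X, alpha)
    kept <- union(always_keep, sel$kept_gene_ids)
    kept <- intersect(gene_ids(X), kept)
    if (length(kept) == 0) stop("variance selection kept no genes")
    before <- n_genes(X)
    Xv <- expression_matrix(X$values[gene_ids(X) %in% kept, , drop = FALSE])
    qc$variance_selection <- list(alpha = alpha, test = sel$test,
                                  note = "variance-significance test is a stand-in; the reference protocol does not specify one",
                                  genes_removed = before - n_genes(Xv))
    X <- Xv
  }
  X <- log_transform(X)
  qc$log_transform <- list(base = 2, pseudocount = 1)
  if (!is.null(top_k)) {
    before <- n_genes(X)
    X <- top_k_by_variance(X, top_k, always_keep)
    qc$top_k_by_variance <- list(k = top_k, genes_removed = before - n_genes(X))
  }
  list(X = X, qc = qc)
}
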