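#' Expression matrix container
#'
#' Lightweight container for a genes-by-cells expression matrix. Rows are
#' genes, columns are cells (or bulk samples). Raw counts are non-negative;
#' after [log_transform()] the `is_log` flag is set and count-based
#' operations refuse the input, enforcing the intended preprocessing order.
#'
#' @param values Numeric matrix, genes in rows, cells in columns.
#' @param gene_ids Character vector of unique gene identifiers. Defaults to
#'   `rownames(values)`.
#' @param cell_ids Character vector of unique cell identifiers. Defaults to
#'   `colnames(values)`.
#' @param is_log Logical; `TRUE` if `values` are already log-transformed.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix, dimnames set), `is_log`, and `transform` (a record of the
#'   log base and pseudocount once applied).
#' @examples
#' x <- expression_matrix(matrix(rpois(20, 5), 4, 5))
#' n_genes(x); n_cells(x)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values), is_log = FALSE) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)")
  if (length(cell_ids) != ncol(values))
    stop("length(cell_ids) must equal ncol(values)")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids are not allowed")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids are not allowed")
  if (!is_log && any(values < 0))
    stop("negative entries are not allowed in a non-log expression matrix")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, is_log = is_log,
                 transform = if (is_log) list(base = NA, pseudocount = NA) else NULL),
            class = "expr_matrix")
}

#' @rdname expression_matrix
#' @param x An `expr_matrix` object.
#' @export
n_genes <- function(x) nrow(x$values)

#' @rdname expression_matrix
#' @export
n_cells <- function(x) ncol(x$values)

#' @rdname expression_matrix
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
cell_ids <- function(x) colnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells (%s)\n",
              n_genes(x), n_cells(x),
              if (x$is_log) "log-transformed" else "raw/normalized counts"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

stopifnot_counts <- function(X, op) {
  if (!inherits(X, "expr_matrix")) stop("expected an 'expr_matrix' object")
  if (X$is_log)
    stop(sprintf("%s() requires a non-log-transformed matrix; apply it before log_transform()", op))
}
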