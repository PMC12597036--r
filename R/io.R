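#' Read an expression matrix from CSV/TSV or MatrixMarket files
#'
#' CSV/TSV layout: header row of cell ids, first column of gene ids, genes in
#' rows. MTX layout: a triplet `.mtx` file plus row-id and column-id sidecar
#' files (one id per line), following the usual CellRanger-style convention
#' but with genes as rows.
#'
#' @param path Path to the `.csv`/`.tsv` (or `.mtx`) file.
#' @param rows,cols For MTX input, paths to the gene-id and cell-id sidecars;
#'   default `<path>.rows` / `<path>.cols`.
#' @param is_log Whether the stored values are already log-transformed.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, rows = NULL, cols = NULL, is_log = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    if (is.null(rows)) rows <- paste0(path, ".rows")
    if (is.null(cols)) cols <- paste0(path, ".cols")
    if (!file.exists(rows) || !file.exists(cols))
      stop("MTX sidecar id files not found: ", rows, ", ", cols)
    m <- as.matrix(Matrix::readMM(path))
    return(expression_matrix(m, gene_ids = readLines(rows),
                             cell_ids = readLines(cols), is_log = is_log))
  }
  sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  expression_matrix(as.matrix(df), is_log = is_log)
}

#' Write an expression matrix
#'
#' @param X An [expression_matrix()].
#' @param path Output path; `.mtx` writes MatrixMarket triplets with `.rows`
#'   and `.cols` sidecars, anything else a delimited table (TSV for `.tsv`,
#'   CSV otherwise).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(X, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(X$values, sparse = TRUE), path)
    writeLines(gene_ids(X), paste0(path, ".rows"))
    writeLines(cell_ids(X), paste0(path, ".cols"))
  } else {
    sep <- if (ext == "tsv") "\t" else ","
    df <- data.frame(gene_id = gene_ids(X), X$values, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a directed edge list into an adjacency matrix
#'
#' Expects a TSV (or whitespace-delimited) file with at least two columns,
#' `regulator` and `target`, optionally a third `weight` column. A header
#' line is auto-detected. Duplicate edges are collapsed and self-loops are
#' dropped, both with a warning (GRN convention: self-regulation is not a
#' predicted link).
#'
#' @param path Edge-list file.
#' @param vocabulary Optional character vector fixing the gene vocabulary and
#'   node order; genes outside it are reported and dropped.
#' @return List with `adjacency` (binary matrix with gene-id dimnames),
#'   `weights` (numeric matrix, NA where no edge), and `dropped_genes`.
#' @export
read_edge_list <- function(path, vocabulary = NULL) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("edge list is empty: ", path)
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad))
    stop(sprintf("malformed edge-list line %d in %s: need >= 2 columns", bad[1], path))
  first <- parts[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3]))) ||
    tolower(first[1]) %in% c("regulator", "source", "tf", "from")
  if (has_header) parts <- parts[-1]
  if (!length(parts)) stop("edge list has a header but no data rows: ", path)
  src <- vapply(parts, `[`, "", 1)
  tgt <- vapply(parts, `[`, "", 2)
  w <- vapply(parts, function(p) if (length(p) >= 3) suppressWarnings(as.numeric(p[3])) else 1, 1.0)
  self <- src == tgt
  if (any(self)) {
    warning(sum(self), " self-loop line(s) dropped")
    src <- src[!self]; tgt <- tgt[!self]; w <- w[!self]
  }
  dropped <- character()
  if (!is.null(vocabulary)) {
    out <- !(src %in% vocabulary & tgt %in% vocabulary)
    dropped <- setdiff(unique(c(src[out], tgt[out])), vocabulary)
    if (length(dropped))
      warning("genes outside the expression vocabulary dropped: ",
              paste(utils::head(dropped, 5), collapse = ", "),
              if (length(dropped) > 5) ", ..." else "")
    src <- src[!out]; tgt <- tgt[!out]; w <- w[!out]
    vocab <- vocabulary
  } else {
    vocab <- sort(unique(c(src, tgt)))
  }
  key <- paste(src, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate edge line(s) collapsed")
    keep <- !duplicated(key)
    src <- src[keep]; tgt <- tgt[keep]; w <- w[keep]
  }
  n <- length(vocab)
  A <- matrix(0, n, n, dimnames = list(vocab, vocab))
  W <- matrix(NA_real_, n, n, dimnames = list(vocab, vocab))
  if (length(src)) {
    idx <- cbind(match(src, vocab), match(tgt, vocab))
    A[idx] <- 1
    W[idx] <- w
  }
  list(adjacency = A, weights = W, dropped_genes = dropped)
}

#' Write an adjacency (or scored edge set) as a TSV edge list
#'
#' @param adjacency Binary adjacency matrix with gene-id dimnames, or a
#'   numeric score matrix when `scores = TRUE`.
#' @param path Output TSV path.
#' @param scores If `TRUE`, write all finite entries ranked by descending
#'   score with a `score` column; otherwise write the edges of a binary
#'   adjacency.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(adjacency, path, scores = FALSE) {
  ids <- rownames(adjacency)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(adjacency)))
  if (scores) {
    idx <- which(is.finite(adjacency), arr.ind = TRUE)
    idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
    sc <- adjacency[idx]
    ord <- order(-sc, ids[idx[, 1]], ids[idx[, 2]])
    df <- data.frame(regulator = ids[idx[ord, 1]], target = ids[idx[ord, 2]],
                     score = sc[ord])
  } else {
    idx <- which(adjacency != 0, arr.ind = TRUE)
    idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
    df <- data.frame(regulator = ids[idx[, 1]], target = ids[idx[, 2]],
                     weight = 1)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a per-gene embedding matrix as TSV
#'
#' Writes `gene_id` plus one column per embedding dimension, and a JSON
#' sidecar (`<path>.json`) recording the seed and configuration so the
#' artifact is self-describing.
#'
#' @param emb Numeric matrix with gene ids as rownames.
#' @param path Output TSV path.
#' @param meta Named list stored in the JSON sidecar.
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(emb, path, meta = list()) {
  df <- data.frame(gene_id = rownames(emb), emb, check.names = FALSE)
  colnames(df) <- c("gene_id", paste0("dim", seq_len(ncol(emb))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an embedding TSV written by [write_embedding()]
#' @param path TSV path.
#' @return Numeric matrix with gene-id rownames.
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
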