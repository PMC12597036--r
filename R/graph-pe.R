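#' Symmetric normalized graph Laplacian
#'
#' `Delta = I - D^{-1/2} A D^{-1/2}` on the symmetrized simple graph.
#' Directed input is symmetrized (`A | t(A)`) first; `D^{-1/2}` is defined
#' as 0 for zero-degree nodes, so isolated nodes contribute a 1 on the
#' diagonal and 0 elsewhere. All eigenvalues lie in [0, 2].
#'
#' @param A Binary adjacency matrix (directed allowed), zero diagonal.
#' @return The n x n normalized Laplacian.
#' @export
normalized_laplacian <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  S <- pmax(A, t(A))
  diag(S) <- 0
  deg <- rowSums(S != 0)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  D <- diag(nrow(S)) - (dinv * S) * rep(dinv, each = nrow(S))
  dimnames(D) <- dimnames(A)
  D
}

#' Laplacian-eigenvector positional encodings
#'
#' Eigendecomposes the normalized Laplacian, discards the trivial
#' eigenvectors (eigenvalue ~ 0, one per connected component, tolerance
#' 1e-8), and returns the next `p` eigenvectors by ascending eigenvalue as
#' node coordinates. Signs are fixed deterministically (each column's first
#' nonzero coordinate is made positive); numerically tied eigenvalues are
#' ordered by lexicographic comparison of the rounded eigenvector entries.
#' When fewer than `p` nontrivial eigenvectors exist, zero columns pad the
#' matrix and `padded` is set.
#'
#' @param A Binary adjacency matrix (symmetrized internally).
#' @param p Number of positional-encoding coordinates per node.
#' @return A `graph_pe` object: `lambda_matrix` (n x p), `eigenvalues`
#'   (the p retained eigenvalues, NA in padded columns), `spectrum` (full
#'   non-decreasing spectrum), `p`, `padded`.
#' @export
laplacian_pe <- function(A, p) {
  p <- as.integer(p)
  if (p < 1) stop("p must be >= 1")
  Delta <- normalized_laplacian(A)
  n <- nrow(Delta)
  eg <- eigen(Delta, symmetric = TRUE)
  ord <- rev(seq_len(n)) # eigen() returns descending; we want ascending
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  # deterministic signs: first coordinate of magnitude > tol made positive
  for (j in seq_len(n)) {
    nz <- which(abs(vecs[, j]) > 1e-10)
    if (length(nz) && vecs[nz[1], j] < 0) vecs[, j] <- -vecs[, j]
  }
  # stable order within numerically tied eigenvalues
  grp <- cumsum(c(TRUE, diff(vals) > 1e-8))
  for (gindex in unique(grp)) {
    cols <- which(grp == gindex)
    if (length(cols) > 1) {
      keys <- apply(round(vecs[, cols, drop = FALSE], 6), 2, paste, collapse = ",")
      vecs[, cols] <- vecs[, cols[order(keys)], drop = FALSE]
    }
  }
  nontrivial <- which(vals > 1e-8)
  take <- nontrivial[seq_len(min(p, length(nontrivial)))]
  lam <- matrix(0, n, p, dimnames = list(rownames(Delta), NULL))
  evals <- rep(NA_real_, p)
  if (length(take)) {
    lam[, seq_along(take)] <- vecs[, take, drop = FALSE]
    evals[seq_along(take)] <- vals[take]
  }
  structure(list(lambda_matrix = lam, eigenvalues = evals, spectrum = vals,
                 p = p, padded = length(take) < p),
            class = "graph_pe")
}

#' @export
print.graph_pe <- function(x, ...) {
  cat(sprintf("<graph_pe> %d nodes x %d coordinates%s\n",
              nrow(x$lambda_matrix), x$p,
              if (x$padded) " (zero-padded)" else ""))
  invisible(x)
}
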