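#' Prior network set
#'
#' A collection of C binary adjacency matrices over one shared gene
#' vocabulary, each representing one previously inferred regulatory network.
#'
#' @param adjacencies List of n x n binary matrices with identical gene-id
#'   dimnames, zero diagonal.
#' @param method_names Character vector naming the source of each network.
#' @return A `prior_set` object.
#' @export
prior_network_set <- function(adjacencies, method_names = names(adjacencies)) {
  if (!length(adjacencies)) stop("at least one prior network is required")
  if (is.null(method_names))
    method_names <- paste0("prior", seq_along(adjacencies))
  d1 <- dim(adjacencies[[1]])
  for (i in seq_along(adjacencies)) {
    A <- adjacencies[[i]]
    if (!all(dim(A) == d1)) stop("prior networks must share one gene vocabulary")
    if (!all(A %in% c(0, 1))) stop("prior adjacencies must be binary")
    if (any(diag(A) != 0)) stop("prior adjacencies must have a zero diagonal")
  }
  structure(list(adjacencies = adjacencies,
                 method_names = as.character(method_names)),
            class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat(sprintf("<prior_set> %d networks over %d genes; edges: %s\n",
              length(x$adjacencies), nrow(x$adjacencies[[1]]),
              paste(vapply(x$adjacencies, function(a) sum(a != 0) / 2, 1),
                    collapse = ", ")))
  invisible(x)
}

mi_binned_matrix <- function(data, bins) {
  n <- nrow(data); m <- ncol(data)
  # equal-frequency discretization per gene
  disc <- t(apply(data, 1, function(x) {
    q <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    if (length(q) < 2) return(rep(1L, length(x)))
    as.integer(cut(x, breaks = q, include.lowest = TRUE))
  }))
  mi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      tab <- table(disc[i, ], disc[j, ]) / m
      px <- rowSums(tab); py <- colSums(tab)
      nz <- tab > 0
      v <- sum(tab[nz] * log(tab[nz] / (outer(px, py)[nz])))
      mi[i, j] <- mi[j, i] <- v
    }
  }
  mi
}

#' Build coexpression prior networks from expression data
#'
#' Plumbing for users without precomputed inferred networks: each method
#' produces a symmetric gene-gene association score matrix, and the top
#' `edges_per_network` scoring gene pairs become binary (undirected) edges.
#' Methods: absolute Pearson / Spearman correlation, binned mutual
#' information, and CLR (the MI matrix z-scored by row and column background
#' before ranking). These scorers stand in for an external inference
#' ensemble; user-supplied edge lists via [read_edge_list()] are the
#' first-class route.
#'
#' @param X A log-transformed [expression_matrix()].
#' @param methods Subset of `c("pearson", "spearman", "mi_binned", "clr")`.
#' @param edges_per_network Number of gene pairs kept per network.
#' @param mi_bins Number of equal-frequency bins for the MI estimate.
#' @return A [prior_network_set()].
#' @export
infer_prior_networks <- function(X, methods = c("pearson", "spearman", "clr"),
                                 edges_per_network, mi_bins = 8) {
  if (!inherits(X, "expr_matrix")) stop("X must be an expr_matrix")
  if (!X$is_log) stop("infer_prior_networks() expects log-transformed input")
  allowed <- c("pearson", "spearman", "mi_binned", "clr")
  if (!all(methods %in% allowed))
    stop("unknown method(s): ", paste(setdiff(methods, allowed), collapse = ", "))
  n <- n_genes(X)
  k_e <- as.integer(edges_per_network)
  if (k_e > n * (n - 1) / 2)
    stop("edges_per_network exceeds the number of gene pairs n(n-1)/2")
  data <- X$values
  mi_cache <- NULL
  get_mi <- function() {
    if (is.null(mi_cache)) mi_cache <<- mi_binned_matrix(data, mi_bins)
    mi_cache
  }
  adjs <- lapply(methods, function(method) {
    S <- switch(method,
      pearson  = abs(stats::cor(t(data), method = "pearson")),
      spearman = abs(stats::cor(t(data), method = "spearman")),
      mi_binned = get_mi(),
      clr = {
        mi <- get_mi()
        diag(mi) <- NA
        mu_r <- rowMeans(mi, na.rm = TRUE); sd_r <- apply(mi, 1, stats::sd, na.rm = TRUE)
        zi <- (mi - mu_r) / pmax(sd_r, 1e-12)
        zj <- t((t(mi) - mu_r) / pmax(sd_r, 1e-12))
        sqrt(pmax(zi, 0)^2 + pmax(zj, 0)^2)
      })
    S[!is.finite(S)] <- 0
    diag(S) <- -Inf # self-association never becomes an edge
    ut <- which(upper.tri(S), arr.ind = TRUE)
    sc <- S[ut]
    ord <- order(-sc, ut[, 1], ut[, 2])[seq_len(k_e)]
    A <- matrix(0, n, n, dimnames = dimnames(data)[c(1, 1)])
    A[ut[ord, , drop = FALSE]] <- 1
    A <- pmax(A, t(A))
    dimnames(A) <- list(rownames(data), rownames(data))
    A
  })
  names(adjs) <- methods
  prior_network_set(adjs, methods)
}
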