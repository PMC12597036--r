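#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' random positive outranks a random negative, ties counted one half. This
#' makes it invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("labels must contain both classes")
  r <- rank(scores) # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration (average precision): scores are grouped by distinct
#' value in descending order and `AP = sum_k P_k * dR_k`, where `P_k` and
#' `R_k` are precision and recall after including the k-th score group.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) stop("labels must contain both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(y)[grp_end]
  np <- grp_end # predictions made so far
  prec <- tp / np
  rec <- tp / n1
  sum(prec * diff(c(0, rec)))
}

#' Topological characteristics of a network
#'
#' All measures are computed on the symmetrized simple graph: maximum
#' degree; degree assortativity (Pearson correlation of endpoint degrees
#' over both orientations of every edge, `NA` when the endpoint degrees
#' have zero variance, e.g. regular graphs); triangle count
#' (`trace(A^3)/6`); global transitivity (3 * triangles / connected
#' triples); and characteristic path length, averaged over connected node
#' pairs only.
#'
#' @param A Binary adjacency matrix; direction is ignored.
#' @param directed Kept for interface clarity; analysis always symmetrizes.
#' @return A `network_characteristics` list with `max_degree`,
#'   `assortativity`, `triangle_count`, `clustering_coefficient`,
#'   `characteristic_path_length`. An empty graph yields all-`NA`.
#' @export
network_characteristics <- function(A, directed = TRUE) {
  A <- as.matrix(A)
  S <- pmax(A, t(A)); diag(S) <- 0
  S <- (S != 0) * 1
  out <- list(max_degree = NA_real_, assortativity = NA_real_,
              triangle_count = NA_real_, clustering_coefficient = NA_real_,
              characteristic_path_length = NA_real_)
  class(out) <- "network_characteristics"
  if (sum(S) == 0) return(out)
  deg <- rowSums(S)
  out$max_degree <- max(deg)
  ends <- which(S == 1, arr.ind = TRUE) # both orientations of each edge
  dx <- deg[ends[, 1]]; dy <- deg[ends[, 2]]
  out$assortativity <- if (stats::sd(dx) == 0 || stats::sd(dy) == 0) NA_real_ else
    stats::cor(dx, dy)
  S3 <- S %*% S %*% S
  tri <- sum(diag(S3)) / 6
  out$triangle_count <- tri
  triples <- sum(deg * (deg - 1) / 2)
  out$clustering_coefficient <- if (triples == 0) 0 else 3 * tri / triples
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected")
  out$characteristic_path_length <- igraph::mean_distance(g, directed = FALSE)
  out
}

#' @export
print.network_characteristics <- function(x, ...) {
  cat(sprintf(paste0("<network_characteristics> max degree %s | assortativity %s | ",
                     "triangles %s | transitivity %s | path length %s\n"),
              format(x$max_degree), format(round(x$assortativity, 4)),
              format(x$triangle_count), format(round(x$clustering_coefficient, 4)),
              format(round(x$characteristic_path_length, 4))))
  invisible(x)
}

#' Pearson agreement between two characteristic records
#'
#' Correlates the ordered characteristic vectors (max degree, assortativity,
#' triangle count, clustering coefficient, characteristic path length) of
#' two networks; fields undefined in either record are excluded pairwise.
#'
#' @param a,b [network_characteristics()] records.
#' @return Pearson correlation coefficient.
#' @export
characteristics_pcc <- function(a, b) {
  fields <- c("max_degree", "assortativity", "triangle_count",
              "clustering_coefficient", "characteristic_path_length")
  va <- unlist(a[fields]); vb <- unlist(b[fields])
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 2) stop("fewer than 2 comparable characteristics")
  stats::cor(va[ok], vb[ok])
}

#' Degree distribution of a network
#'
#' Histogram of symmetrized degrees, including the zero-degree bin.
#'
#' @param A Binary adjacency matrix.
#' @return List with `degree` (sorted unique degrees) and `count`.
#' @export
degree_distribution <- function(A) {
  A <- as.matrix(A)
  S <- pmax(A, t(A)); diag(S) <- 0
  deg <- rowSums(S != 0)
  tab <- table(deg)
  list(degree = as.integer(names(tab)), count = as.integer(tab))
}

#' Log-log degree distribution plot
#'
#' Zero-count bins are excluded (log of zero); the zero-degree bin is also
#' dropped on the log-degree axis.
#'
#' @param A Binary adjacency matrix (or a list of named adjacencies to
#'   overlay).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the degree distribution(s).
#' @export
plot_degree_loglog <- function(A, ...) {
  As <- if (is.list(A) && !is.matrix(A)) A else list(network = A)
  dds <- lapply(As, degree_distribution)
  cols <- seq_along(dds)
  first <- TRUE
  for (i in seq_along(dds)) {
    dd <- dds[[i]]
    keep <- dd$degree > 0 & dd$count > 0
    if (!any(keep)) next
    if (first) {
      graphics::plot(dd$degree[keep], dd$count[keep], log = "xy", col = cols[i],
                     pch = 19, xlab = "degree", ylab = "count", ...)
      first <- FALSE
    } else graphics::points(dd$degree[keep], dd$count[keep], col = cols[i], pch = 19)
  }
  if (length(dds) > 1)
    graphics::legend("topright", legend = names(dds), col = cols, pch = 19, bty = "n")
  invisible(dds)
}

#' Binarize a score matrix into a top-k adjacency
#'
#' The `k_edges` highest-scoring ordered pairs become directed edges; ties
#' are broken by (source, target) lexicographic order of the gene ids (row
#' then column index when unnamed). The diagonal is ignored.
#'
#' @param score_matrix Numeric matrix of pair scores (NaN/NA allowed).
#' @param k_edges Number of edges to keep.
#' @return Binary adjacency of the same shape and dimnames.
#' @export
binarize_scores <- function(score_matrix, k_edges) {
  sm <- as.matrix(score_matrix)
  diag(sm) <- NA
  idx <- which(is.finite(sm), arr.ind = TRUE)
  if (k_edges > nrow(idx)) stop("k_edges exceeds the number of finite scores")
  ids_r <- rownames(sm) %||% sprintf("%09d", seq_len(nrow(sm)))
  ids_c <- colnames(sm) %||% sprintf("%09d", seq_len(ncol(sm)))
  sc <- sm[idx]
  ord <- order(-sc, ids_r[idx[, 1]], ids_c[idx[, 2]])[seq_len(k_edges)]
  A <- matrix(0, nrow(sm), ncol(sm), dimnames = dimnames(sm))
  A[idx[ord, , drop = FALSE]] <- 1
  A
}
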