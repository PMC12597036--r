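# Shared fixtures, built in code at test time.

toy_counts <- function(n = 20, m = 10, seed = 1, lambda = 5) {
  set.seed(seed)
  expression_matrix(matrix(stats::rpois(n * m, lambda), n, m))
}

# Directed cycle 1 -> 2 -> ... -> n -> 1
cycle_adjacency <- function(n) {
  A <- matrix(0, n, n, dimnames = list(paste0("g", seq_len(n)),
                                       paste0("g", seq_len(n))))
  A[cbind(seq_len(n), c(2:n, 1))] <- 1
  A
}

random_adjacency <- function(n, p = 0.3, seed = 1, symmetric = FALSE) {
  set.seed(seed)
  A <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
  diag(A) <- 0
  if (symmetric) A <- pmax(A, t(A))
  A
}

# Brute-force network characteristics: BFS distances, triple enumeration.
brute_characteristics <- function(A) {
  S <- pmax(A, t(A)); diag(S) <- 0; S <- (S != 0) * 1
  n <- nrow(S)
  if (sum(S) == 0)
    return(list(max_degree = NA_real_, assortativity = NA_real_,
                triangle_count = NA_real_, clustering_coefficient = NA_real_,
                characteristic_path_length = NA_real_))
  deg <- rowSums(S)
  tri <- 0; triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k) {
      e <- S[i, j] + S[i, k] + S[j, k]
      if (e == 3) tri <- tri + 1
    }
  }
  for (ctr in seq_len(n)) {
    d <- deg[ctr]
    triples <- triples + d * (d - 1) / 2
  }
  # all-pairs BFS
  dist_sum <- 0; pairs <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(S[v, ] == 1)) if (dist[u] == Inf) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
      }
      frontier <- nxt
    }
    reach <- which(is.finite(dist) & seq_len(n) != s)
    dist_sum <- dist_sum + sum(dist[reach])
    pairs <- pairs + length(reach)
  }
  ends <- which(S == 1, arr.ind = TRUE)
  dx <- deg[ends[, 1]]; dy <- deg[ends[, 2]]
  assort <- if (stats::sd(dx) == 0 || stats::sd(dy) == 0) NA_real_ else
    stats::cor(dx, dy)
  list(max_degree = max(deg), assortativity = assort, triangle_count = tri,
       clustering_coefficient = if (triples == 0) 0 else 3 * tri / triples,
       characteristic_path_length = if (pairs == 0) NA_real_ else dist_sum / pairs)
}

# Exhaustive AUROC oracle: fraction of concordant positive/negative pairs,
# ties counted one half.
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
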