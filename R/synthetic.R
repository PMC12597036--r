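#' Generate a ground-truth regulatory network
#'
#' Directed graph with no self-loops. `scale_free` grows edges by
#' preferential attachment on target in-degree (regulatory hubs emerge as
#' high-in-degree targets); `erdos_renyi` samples ordered pairs uniformly.
#' The edge count is `round(n * mean_out_degree)`.
#'
#' @param n Number of genes (>= 10).
#' @param mean_out_degree Average out-degree; edge count = `n * mean_out_degree`.
#' @param model `"scale_free"` or `"erdos_renyi"`.
#' @param seed Integer seed.
#' @return Binary adjacency matrix (regulator rows, target columns) with
#'   gene ids `g1..gn`.
#' @export
generate_grn <- function(n, mean_out_degree = 3, model = c("scale_free", "erdos_renyi"),
                         seed = 1) {
  model <- match.arg(model)
  n <- as.integer(n)
  if (n < 10) stop("n must be >= 10")
  E <- round(n * mean_out_degree)
  if (E > n * (n - 1)) stop("infeasible density: mean_out_degree too large for n")
  set.seed(as.integer(seed))
  ids <- paste0("g", seq_len(n))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (model == "erdos_renyi") {
    pool <- which(diag(n) == 0)
    A[sample(pool, E)] <- 1
  } else {
    indeg <- rep(0, n)
    added <- 0
    attempts <- 0
    while (added < E) {
      attempts <- attempts + 1
      if (attempts > 100 * E) stop("infeasible density: could not place edges")
      src <- sample.int(n, 1)
      wts <- indeg + 1
      wts[src] <- 0
      tgt <- sample.int(n, 1, prob = wts)
      if (A[src, tgt] == 0) {
        A[src, tgt] <- 1
        indeg[tgt] <- indeg[tgt] + 1
        added <- added + 1
      }
    }
  }
  A
}

# Greedy linear-arrangement heuristic (Eades-Lin-Smyth): returns edges
# pointing backwards in the computed order; removing them leaves a DAG.
feedback_edges <- function(A) {
  n <- nrow(A)
  act <- rep(TRUE, n)
  left <- integer(0); right <- integer(0)
  Aw <- A != 0
  while (any(act)) {
    outd <- rowSums(Aw[, act, drop = FALSE][act, , drop = FALSE])
    ind <- colSums(Aw[act, act, drop = FALSE])
    nodes <- which(act)
    sinks <- nodes[outd == 0]
    if (length(sinks)) {
      right <- c(sinks[length(sinks)], right); act[sinks[length(sinks)]] <- FALSE; next
    }
    sources <- nodes[ind == 0]
    if (length(sources)) {
      left <- c(left, sources[1]); act[sources[1]] <- FALSE; next
    }
    pick <- nodes[which.max(outd - ind)]
    left <- c(left, pick); act[pick] <- FALSE
  }
  ord <- c(left, right)
  pos <- integer(n); pos[ord] <- seq_len(n)
  e <- which(A != 0, arr.ind = TRUE)
  e[pos[e[, 1]] >= pos[e[, 2]], , drop = FALSE]
}

#' Simulate expression data from a regulatory network
#'
#' Linear structural-equation propagation: feedback edges (identified by a
#' greedy linear-arrangement heuristic) are removed for simulation only, the
#' remaining DAG is evaluated in topological order with each gene equal to
#' the weighted sum of its regulators plus Gaussian noise, regulator weights
#' drawn as `+/- U(0.5, 1.5)`. Root genes are standard normal. Propagation
#' is variance-stabilized: the regulatory signal of each gene is scaled to
#' unit variance before noise of standard deviation `noise_sd` is mixed in,
#' so regulation strength (the signal-to-noise ratio) is uniform across the
#' network depth rather than decaying along regulatory chains. The
#' standardized values are mapped to non-negative counts through
#' `round(exp(2 * x))` -- a wide log-normal-like count distribution whose
#' rounding produces realistic structural zeros -- and Bernoulli dropout
#' zeroes entries to emulate scRNA-seq technical dropout.
#'
#' @param A_true Directed binary adjacency (regulator rows, target columns).
#' @param m_cells Number of cells to simulate.
#' @param noise_sd Standard deviation of the propagation noise.
#' @param dropout_rate Probability of zeroing an entry, in [0, 1).
#' @param seed Integer seed.
#' @return A raw-count [expression_matrix()]; attributes `latent` (the
#'   pre-count SEM values), `edge_weights`, and `feedback_removed` record the
#'   generative state.
#' @export
simulate_expression <- function(A_true, m_cells, noise_sd = 1,
                                dropout_rate = 0.3, seed = 1) {
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must lie in [0, 1)")
  set.seed(as.integer(seed))
  n <- nrow(A_true)
  fb <- feedback_edges(A_true)
  Ad <- A_true
  if (nrow(fb)) Ad[fb] <- 0
  W <- matrix(0, n, n, dimnames = dimnames(A_true))
  ne <- sum(Ad != 0)
  W[Ad != 0] <- sample(c(-1, 1), ne, replace = TRUE) * stats::runif(ne, 0.5, 1.5)
  # topological order of the DAG
  indeg <- colSums(Ad)
  order_ <- integer(0)
  avail <- which(indeg == 0)
  indeg_w <- indeg
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    order_ <- c(order_, v)
    kids <- which(Ad[v, ] != 0)
    for (k in kids) {
      indeg_w[k] <- indeg_w[k] - 1
      if (indeg_w[k] == 0) avail <- c(avail, k)
    }
  }
  X <- matrix(0, n, m_cells)
  for (v in order_) {
    parents <- which(Ad[, v] != 0)
    if (!length(parents)) {
      X[v, ] <- stats::rnorm(m_cells)
    } else {
      signal <- as.vector(W[parents, v] %*% X[parents, , drop = FALSE])
      s <- stats::sd(signal)
      if (s > 0) signal <- signal / s
      X[v, ] <- (signal + (if (noise_sd > 0) stats::rnorm(m_cells, 0, noise_sd) else 0)) /
        sqrt(1 + noise_sd^2)
    }
  }
  latent <- X
  sds <- apply(X, 1, stats::sd)
  Xs <- (X - rowMeans(X)) / ifelse(sds > 0, sds, 1)
  counts <- round(exp(2 * Xs))
  if (dropout_rate > 0)
    counts[matrix(stats::runif(length(counts)) < dropout_rate,
                  nrow(counts))] <- 0
  out <- expression_matrix(counts, gene_ids = rownames(A_true),
                           cell_ids = paste0("c", seq_len(m_cells)))
  attr(out, "latent") <- latent
  attr(out, "edge_weights") <- W
  attr(out, "feedback_removed") <- fb
  out
}

#' Corrupt a network into an imperfect "inferred" prior
#'
#' Keeps `keep_fraction` of the true edges and replaces the rest with
#' uniformly sampled false edges, preserving the edge count, so the prior's
#' precision against the truth equals `keep_fraction` by construction.
#'
#' @param A_true Directed binary adjacency.
#' @param keep_fraction Fraction of true edges retained, in (0, 1].
#' @param seed Integer seed.
#' @return Binary adjacency with the same dimnames and edge count.
#' @export
corrupt_network <- function(A_true, keep_fraction, seed = 1) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must lie in (0, 1]")
  set.seed(as.integer(seed))
  edges <- which(A_true != 0)
  E <- length(edges)
  nkeep <- round(keep_fraction * E)
  kept <- if (nkeep == E) edges else sample(edges, nkeep)
  n <- nrow(A_true)
  nonedges <- setdiff(which(A_true == 0 & diag(n) == 0), edges)
  fake <- if (E - nkeep > 0) sample(nonedges, E - nkeep) else integer(0)
  A <- matrix(0, n, n, dimnames = dimnames(A_true))
  A[c(kept, fake)] <- 1
  A
}

#' Generate a complete synthetic benchmark bundle
#'
#' Composes [generate_grn()], [simulate_expression()], [corrupt_network()]
#' and [make_splits()] into one reproducible bundle whose defaults define
#' the benchmark conditions: 100 genes, 200 cells, mean out-degree 3
#' (scale-free), 3 prior networks at 80% edge fidelity, unit propagation
#' noise (per-hop signal-to-noise 1:1), dropout 0.3, 80/10/10 edge splits with 1:1 negatives. The manifest
#' (all parameters plus the seed) regenerates the bundle bit-identically.
#'
#' @param n,m_cells,mean_out_degree,model,noise_sd,dropout_rate Passed to
#'   the generators.
#' @param n_priors,keep_fraction Number of corrupted prior networks and
#'   their edge fidelity.
#' @param split_ratios,negative_ratio Passed to [make_splits()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param dir Optional directory: writes the expression CSV, edge-list TSVs
#'   and a JSON manifest.
#' @return A `benchmark_bundle`: `A_true`, `X` (raw counts), `priors`,
#'   `splits`, `manifest`.
#' @export
make_benchmark <- function(n = 100, m_cells = 200, mean_out_degree = 3,
                           model = "scale_free", n_priors = 3,
                           keep_fraction = 0.8, noise_sd = 1,
                           dropout_rate = 0.3, split_ratios = c(0.8, 0.1, 0.1),
                           negative_ratio = 1, seed = 1, dir = NULL) {
  manifest <- list(n = n, m_cells = m_cells, mean_out_degree = mean_out_degree,
                   model = model, n_priors = n_priors,
                   keep_fraction = keep_fraction, noise_sd = noise_sd,
                   dropout_rate = dropout_rate, split_ratios = split_ratios,
                   negative_ratio = negative_ratio, seed = seed)
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max %/% 2, 3 + n_priors)
  A_true <- generate_grn(n, mean_out_degree, model, seed = sub[1])
  X <- simulate_expression(A_true, m_cells, noise_sd, dropout_rate, seed = sub[2])
  priors <- prior_network_set(
    lapply(seq_len(n_priors), function(i)
      corrupt_network(A_true, keep_fraction, seed = sub[3 + i])),
    paste0("prior", seq_len(n_priors)))
  true_edges <- which(A_true != 0, arr.ind = TRUE)
  splits <- make_splits(true_edges, n, ratios = split_ratios,
                        negative_ratio = negative_ratio, seed = sub[3])
  bundle <- structure(list(A_true = A_true, X = X, priors = priors,
                           splits = splits, manifest = manifest),
                      class = "benchmark_bundle")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_expression(X, file.path(dir, "expression.csv"))
    write_edge_list(A_true, file.path(dir, "true_network.tsv"))
    for (i in seq_len(n_priors))
      write_edge_list(priors$adjacencies[[i]],
                      file.path(dir, sprintf("prior_%d.tsv", i)))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat(sprintf("<benchmark_bundle> %d genes, %d cells, %d true edges, %d priors (seed %d)\n",
              nrow(x$A_true), n_cells(x$X), sum(x$A_true != 0),
              length(x$priors$adjacencies), x$manifest$seed))
  invisible(x)
}
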