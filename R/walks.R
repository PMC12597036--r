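#' Sample a random-walk corpus from a set of prior networks
#'
#' Converts each prior network into "sentences": for every non-isolated node,
#' `walks_per_node` uniform first-order random walks of `walk_length` node
#' tokens are drawn on the symmetrized adjacency (node2vec with p = q = 1),
#' and each sequence is prefixed with a `[CLS]` token. Edge direction is used
#' only through symmetrization here; stored networks keep their direction.
#' Nodes isolated after symmetrization are skipped; a network with no usable
#' node is an error.
#'
#' @param priors A [prior_network_set()] (or a single adjacency matrix).
#' @param walk_length Number of gene tokens per walk (default 20).
#' @param walks_per_node Walks started from each non-isolated node per
#'   network (default 10).
#' @param directed If `TRUE`, walks follow edge direction instead of the
#'   symmetrized adjacency; any walk reaching a node without out-neighbors
#'   is an error (regulatory sink), which is why symmetrization is the
#'   default.
#' @param seed Integer seed; the corpus is deterministic given it.
#' @return A `walk_corpus` object: `sequences` (integer matrix, one sequence
#'   per row, `walk_length + 1` columns, first column `[CLS]`), `vocabulary`
#'   (gene ids followed by `[CLS]`, `[MASK]`, `[PAD]`), token-id constants
#'   `cls_id`/`mask_id`/`pad_id`, `n_genes`, and the sampling parameters.
#' @export
sample_walks <- function(priors, walk_length = 20, walks_per_node = 10,
                         directed = FALSE, seed = 1) {
  if (is.matrix(priors)) priors <- prior_network_set(list(priors), "prior1")
  if (!inherits(priors, "prior_set")) stop("priors must be a prior_network_set")
  n <- nrow(priors$adjacencies[[1]])
  ids <- rownames(priors$adjacencies[[1]]) %||% paste0("g", seq_len(n))
  walk_length <- as.integer(walk_length)
  set.seed(as.integer(seed))
  seqs <- list()
  for (ci in seq_along(priors$adjacencies)) {
    A <- priors$adjacencies[[ci]]
    S <- if (directed) A else pmax(A, t(A))
    nbrs <- lapply(seq_len(n), function(i) which(S[i, ] != 0))
    usable <- which(lengths(nbrs) > 0)
    if (!length(usable))
      stop(sprintf("network '%s' has no usable edges; cannot walk",
                   priors$method_names[ci]))
    for (v in usable) {
      for (r in seq_len(walks_per_node)) {
        walk <- integer(walk_length)
        walk[1] <- v
        cur <- v
        if (walk_length > 1) for (s in 2:walk_length) {
          nb <- nbrs[[cur]]
          if (!length(nb))
            stop(sprintf("directed walk dead-ends at node %d in network '%s'; use directed = FALSE",
                         cur, priors$method_names[ci]))
          cur <- if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
          walk[s] <- cur
        }
        seqs[[length(seqs) + 1]] <- walk
      }
    }
  }
  mat <- cbind(n + 1L, do.call(rbind, seqs))
  dimnames(mat) <- NULL
  structure(list(sequences = mat,
                 vocabulary = c(ids, "[CLS]", "[MASK]", "[PAD]"),
                 cls_id = n + 1L, mask_id = n + 2L, pad_id = n + 3L,
                 n_genes = n, walk_length = walk_length,
                 walks_per_node = as.integer(walks_per_node),
                 seed = as.integer(seed)),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("<walk_corpus> %d sequences of %d gene tokens (+[CLS]) over %d genes\n",
              nrow(x$sequences), x$walk_length, x$n_genes))
  invisible(x)
}

#' Export a walk corpus as plain text (one sequence per line)
#' @param corpus A [sample_walks()] corpus.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  lines <- apply(corpus$sequences, 1, function(s)
    paste(corpus$vocabulary[s], collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
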