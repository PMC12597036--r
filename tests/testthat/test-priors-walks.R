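test_that("prior network scorers produce valid binary networks", {
  set.seed(3)
  X <- log_transform(toy_counts(n = 15, m = 40, seed = 3))
  ps <- infer_prior_networks(X, c("pearson", "spearman", "mi_binned", "clr"),
                             edges_per_network = 20)
  expect_length(ps$adjacencies, 4)
  for (A in ps$adjacencies) {
    expect_true(all(A %in% c(0, 1)))
    expect_true(all(diag(A) == 0))
    expect_equal(A, t(A))
    expect_equal(sum(A) / 2, 20)
  }
  expect_error(infer_prior_networks(X, "pearson", edges_per_network = 1000),
               "exceeds")
  expect_error(infer_prior_networks(X, "kendall", edges_per_network = 5),
               "unknown method")
})

test_that("perfectly correlated genes form the top pearson edge", {
  set.seed(4)
  base <- stats::rnorm(30)
  vals <- rbind(base, base * 2, matrix(stats::rnorm(8 * 30), 8, 30))
  rownames(vals) <- NULL
  X <- expression_matrix(vals + 20, is_log = TRUE)
  ps <- infer_prior_networks(X, "pearson", edges_per_network = 1)
  expect_equal(ps$adjacencies[[1]]["g1", "g2"], 1)
})

test_that("scorers recover planted structure above a degree-preserving null", {
  bench <- make_benchmark(n = 40, m_cells = 120, dropout_rate = 0.1, seed = 5)
  X <- log_transform(bench$X)
  truth <- pmax(bench$A_true, t(bench$A_true))
  k_e <- sum(bench$A_true)
  ps <- infer_prior_networks(X, c("pearson", "clr"), edges_per_network = k_e)
  set.seed(99)
  for (i in seq_along(ps$adjacencies)) {
    A <- ps$adjacencies[[i]]
    hits <- sum(A * truth) / 2
    # degree-preserving null: igraph rewiring of the scored network
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    null_hits <- replicate(20, {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 200))
      sum(igraph::as_adjacency_matrix(gr, sparse = FALSE) * truth) / 2
    })
    expect_gt(hits, stats::quantile(null_hits, 0.95),
              label = sprintf("%s planted-edge recovery", ps$method_names[i]))
  }
})

test_that("random walks respect the graph and corpus accounting", {
  # 2-node single-edge graph: walks alternate the two tokens
  A <- matrix(0, 2, 2); A[1, 2] <- 1
  co <- sample_walks(A, walk_length = 6, walks_per_node = 3, seed = 1)
  expect_equal(nrow(co$sequences), 2 * 3)
  for (r in seq_len(nrow(co$sequences))) {
    s <- co$sequences[r, ]
    expect_equal(s[1], co$cls_id)
    expect_true(all(abs(diff(s[-1])) == 1)) # alternation between tokens 1,2
  }
  # corpus size = sum over networks of non-isolated nodes x walks_per_node
  B1 <- matrix(0, 5, 5); B1[1, 2] <- 1; B1[2, 3] <- 1 # nodes 4,5 isolated
  B2 <- matrix(0, 5, 5); B2[4, 5] <- 1                # nodes 1,2,3 isolated
  ps <- prior_network_set(list(B1, B2), c("chain", "pair"))
  co2 <- sample_walks(ps, walk_length = 4, walks_per_node = 2, seed = 2)
  expect_equal(nrow(co2$sequences), (3 + 2) * 2)
  # all-isolated network errors with its name
  empty <- matrix(0, 3, 3)
  expect_error(sample_walks(prior_network_set(list(empty), "void"), 4, 1),
               "void")
})

test_that("directed walks follow edge direction and dead-end loudly", {
  A <- cycle_adjacency(5)
  co <- sample_walks(A, walk_length = 6, walks_per_node = 1, directed = TRUE,
                     seed = 3)
  for (r in seq_len(nrow(co$sequences))) {
    s <- co$sequences[r, -1]
    expect_true(all(diff(s) %% 5 == 1)) # successor is always +1 mod n
  }
  chain <- matrix(0, 3, 3); chain[1, 2] <- 1; chain[2, 3] <- 1
  expect_error(sample_walks(chain, walk_length = 5, walks_per_node = 1,
                            directed = TRUE, seed = 1), "dead-end")
})

test_that("walk corpus is deterministic under its seed", {
  A <- random_adjacency(10, 0.3, seed = 7)
  c1 <- sample_walks(A, 8, 4, seed = 42)
  c2 <- sample_walks(A, 8, 4, seed = 42)
  c3 <- sample_walks(A, 8, 4, seed = 43)
  expect_identical(c1$sequences, c2$sequences)
  expect_false(identical(c1$sequences, c3$sequences))
})

test_that("sequence positional encoding matches its closed form", {
  p_dim <- 16
  expect_equal(sequence_positional_encoding(0, 0, p_dim), 0)
  expect_equal(sequence_positional_encoding(0, 2, p_dim), 0)
  expect_equal(sequence_positional_encoding(0, 1, p_dim), 1)
  expect_equal(sequence_positional_encoding(0, 7, p_dim), 1)
  expect_equal(sequence_positional_encoding(1, 0, 8), sin(1))
  expect_equal(sequence_positional_encoding(1, 0, 100), sin(1))
  expect_equal(sequence_positional_encoding(3, 4, 10),
               sin(3 / 10000^(4 / 10)))
  expect_equal(sequence_positional_encoding(3, 5, 10),
               cos(3 / 10000^(4 / 10)))
  expect_error(sequence_positional_encoding(1, 20, 10), "p_dim")
})

test_that("positional encoding is a pure bounded function (property)", {
  set.seed(10)
  for (rep in 1:200) {
    p_dim <- sample(2:64, 1)
    pos <- sample(0:500, 1)
    i <- sample(0:(p_dim - 1), 1)
    v1 <- sequence_positional_encoding(pos, i, p_dim)
    v2 <- sequence_positional_encoding(pos, i, p_dim)
    expect_identical(v1, v2)
    expect_true(v1 >= -1 && v1 <= 1)
  }
})

test_that("masking hits exactly round(rate * L) gene tokens, never CLS", {
  A <- random_adjacency(12, 0.4, seed = 2)
  co <- sample_walks(A, walk_length = 20, walks_per_node = 2, seed = 2)
  mk <- mask_tokens(co, 0.2, seed = 9)
  expect_true(all(rowSums(mk$mask) == 4)) # round(0.2 * 20)
  expect_true(all(!mk$mask[, 1]))
  expect_true(all(mk$masked_sequences[mk$mask] == co$mask_id))
  expect_identical(mk$labels, co$sequences)
  # rounding: rate 0.5 on walk length 2 -> 1 masked
  co2 <- sample_walks(A, walk_length = 2, walks_per_node = 1, seed = 2)
  expect_true(all(rowSums(mask_tokens(co2, 0.5, 1)$mask) == 1))
  expect_error(mask_tokens(co2, 0.1, 1), "longer walks")
})

test_that("CLS is never masked over many seeded draws", {
  A <- random_adjacency(8, 0.5, seed = 3)
  co <- sample_walks(A, walk_length = 5, walks_per_node = 1, seed = 3)
  cls_hit <- FALSE
  for (s in 1:1000) {
    mk <- mask_tokens(co, 0.2, seed = s)
    if (any(mk$mask[, 1])) { cls_hit <- TRUE; break }
  }
  expect_false(cls_hit)
})

test_that("mlm_loss counts only masked positions", {
  B <- 2; L <- 3; V <- 4
  labels <- matrix(c(1, 2, 3, 4, 1, 2), B, L, byrow = TRUE)
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE), B, L, byrow = TRUE)
  # perfect one-hot predictions -> loss 0
  probs <- array(1e-12, c(B, L, V))
  for (b in 1:B) for (l in 1:L) probs[b, l, labels[b, l]] <- 1
  expect_equal(mlm_loss(probs, labels, mask), 0, tolerance = 1e-9)
  # uniform prediction, one masked token -> log(V)
  uni <- array(1 / V, c(B, L, V))
  one <- matrix(FALSE, B, L); one[1, 1] <- TRUE
  expect_equal(mlm_loss(uni, labels, one), log(V))
  # perturbing unmasked predictions leaves the loss unchanged
  probs2 <- probs
  probs2[1, 2, ] <- stats::runif(V)
  expect_equal(mlm_loss(probs2, labels, mask), mlm_loss(probs, labels, mask))
  expect_error(mlm_loss(probs, labels, matrix(FALSE, B, L)), "no masked")
})
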