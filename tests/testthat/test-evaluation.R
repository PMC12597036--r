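test_that("auroc matches the rank definition on edge cases", {
  expect_equal(auroc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(auroc(c(0.1, 0.9), c(1, 0)), 0.0)
  expect_equal(auroc(c(0.5, 0.5, 0.5), c(1, 0, 1)), 0.5)
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("auroc equals exhaustive concordant-pair counting (n <= 12)", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    scores <- sample(round(stats::runif(n), 2), n) # ties likely
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))[seq_len(n)]
    expect_equal(auroc(scores, labels), brute_auroc(scores, labels))
  }
})

test_that("auroc is invariant under strictly monotone score transforms", {
  set.seed(7)
  scores <- stats::rnorm(40)
  labels <- stats::rbinom(40, 1, 0.4)
  a <- auroc(scores, labels)
  expect_equal(auroc(exp(scores), labels), a)
  expect_equal(auroc(2 * scores + 5, labels), a)
  expect_equal(auroc(rank(scores), labels), a)
})

test_that("auprc step integration behaves on known cases", {
  # perfect ranking: AP = 1
  expect_equal(auprc(c(3, 2, 1), c(1, 1, 0)), 1)
  # ranking 1,0,1: P at ranks 1 and 3 -> (1 + 2/3)/2
  expect_equal(auprc(c(0.9, 0.8, 0.1), c(1, 0, 1)), (1 + 2 / 3) / 2)
  # all tied: single group, AP = prevalence
  expect_equal(auprc(c(1, 1, 1, 1), c(1, 0, 1, 0)), 0.5)
  expect_error(auprc(c(1, 2), c(1, 1)), "both classes")
})

test_that("network characteristics match hand-derived small graphs", {
  K3 <- matrix(1, 3, 3) - diag(3)
  nc <- network_characteristics(K3)
  expect_equal(nc$max_degree, 2)
  expect_equal(nc$triangle_count, 1)
  expect_equal(nc$clustering_coefficient, 1)
  expect_equal(nc$characteristic_path_length, 1)
  expect_true(is.na(nc$assortativity)) # regular graph: undefined, not 0

  star <- matrix(0, 4, 4); star[1, 2:4] <- 1
  ns <- network_characteristics(star)
  expect_equal(ns$max_degree, 3)
  expect_equal(ns$triangle_count, 0)
  expect_equal(ns$clustering_coefficient, 0)
  expect_equal(ns$characteristic_path_length, 1.5)
  expect_equal(ns$assortativity, -1)

  path3 <- matrix(0, 3, 3); path3[1, 2] <- 1; path3[2, 3] <- 1
  expect_equal(network_characteristics(path3)$characteristic_path_length, 4 / 3)

  empty <- network_characteristics(matrix(0, 4, 4))
  expect_true(all(is.na(unlist(empty))))
})

test_that("network characteristics agree with a brute-force oracle", {
  # every labelled graph on 4 nodes (64 of them), then random graphs to n=8
  combos <- expand.grid(rep(list(0:1), 6))
  ut <- which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE)
  for (r in seq_len(nrow(combos))) {
    A <- matrix(0, 4, 4)
    A[ut] <- as.numeric(combos[r, ])
    A <- pmax(A, t(A))
    got <- network_characteristics(A)
    want <- brute_characteristics(A)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], info = paste("field", f, "graph", r))
  }
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(5:8, 1)
    A <- random_adjacency(n, p = stats::runif(1, 0.1, 0.7), seed = rep)
    got <- network_characteristics(A)
    want <- brute_characteristics(A)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], info = paste("rand", rep, f))
  }
})

test_that("characteristics PCC handles affine relations and NAs", {
  a <- structure(list(max_degree = 10, assortativity = -0.5,
                      triangle_count = 30, clustering_coefficient = 0.2,
                      characteristic_path_length = 2.5),
                 class = "network_characteristics")
  expect_equal(characteristics_pcc(a, a), 1)
  b <- a; for (f in names(b)) b[[f]] <- 2 * b[[f]] + 1
  expect_equal(characteristics_pcc(a, b), 1)
  anti <- a; for (f in names(anti)) anti[[f]] <- -a[[f]]
  expect_lt(characteristics_pcc(a, anti), 0)
  a_na <- a; a_na$assortativity <- NA_real_
  expect_equal(characteristics_pcc(a_na, b), 1) # pairwise exclusion
  short <- a; for (f in names(short)[1:4]) short[[f]] <- NA_real_
  expect_error(characteristics_pcc(short, b), "fewer than 2")
})

test_that("degree distribution includes the zero bin and sums to n", {
  K3 <- matrix(1, 3, 3) - diag(3)
  dd <- degree_distribution(K3)
  expect_equal(dd$degree, 2L); expect_equal(dd$count, 3L)
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1
  ds <- degree_distribution(star)
  expect_equal(ds$degree, c(1L, 3L)); expect_equal(ds$count, c(3L, 1L))
  iso <- matrix(0, 5, 5); iso[1, 2] <- 1
  di <- degree_distribution(iso)
  expect_equal(sum(di$count), 5L)
  expect_true(0L %in% di$degree)
})

test_that("binarize_scores keeps exactly k edges with lexicographic ties", {
  sm <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  sm["a", "b"] <- 5; sm["c", "a"] <- 4; sm["b", "c"] <- 3
  top1 <- binarize_scores(sm, 1)
  expect_equal(sum(top1), 1); expect_equal(top1["a", "b"], 1)
  tied <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  t2 <- binarize_scores(tied, 2)
  expect_equal(sum(t2), 2)
  expect_equal(t2["a", "b"], 1); expect_equal(t2["a", "c"], 1) # (a,b) < (a,c)
  expect_equal(sum(binarize_scores(matrix(stats::rnorm(25), 5, 5), 7)), 7)
  expect_error(binarize_scores(tied, 100), "exceeds")
})
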