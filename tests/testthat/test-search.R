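# Metrics, k-NN retrieval, Neighbor-Joining and Newick serialization.

test_that("distances follow their closed forms", {
  x <- rnorm(10)
  expect_equal(pairwise_distance(x, x), 0)
  expect_equal(pairwise_distance(x, x, metric_config("lk_norm", 0.3)), 0)
  expect_equal(pairwise_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(pairwise_distance(c(0, 0), c(1, 1), metric_config("lk_norm", 0.3)),
               2^(1 / 0.3))
  expect_equal(pairwise_distance(c(0, 0), c(3, 4), metric_config("lk_norm", 2)), 5)
  expect_error(pairwise_distance(1:3, 1:4), "length mismatch")
})

test_that("euclidean satisfies the triangle inequality on random triples", {
  set.seed(61)
  for (i in 1:50) {
    a <- rnorm(8); b <- rnorm(8); c <- rnorm(8)
    expect_lte(pairwise_distance(a, c),
               pairwise_distance(a, b) + pairwise_distance(b, c) + 1e-12)
  }
})

test_that("the fractional Lk-norm is a dissimilarity, not a metric", {
  # a concrete triangle-inequality violation at k = 0.3
  a <- c(0, 0); b <- c(1, 0); c <- c(1, 1)
  lk <- metric_config("lk_norm", 0.3)
  expect_gt(pairwise_distance(a, c, lk),
            pairwise_distance(a, b, lk) + pairwise_distance(b, c, lk))
})

test_that("distance matrices are symmetric with a zero diagonal under both metrics", {
  fit <- fixture_fit()
  for (m in list(metric_config("euclidean"), metric_config("lk_norm", 0.3))) {
    D <- distance_matrix(fit$tm$wtxt[1:8, ], m)
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, 8))
    expect_equal(D[2, 5], pairwise_distance(fit$tm$wtxt[2, ], fit$tm$wtxt[5, ], m))
  }
})

test_that("k-NN matches a full-sort oracle, breaks ties by label, handles bounds", {
  set.seed(62)
  m <- matrix(rnorm(200 * 6), 200, 6)
  rownames(m) <- sprintf("R%03d", sample(200))
  q <- rnorm(6)
  for (metric in list(metric_config("euclidean"), metric_config("lk_norm", 0.3))) {
    got <- knn_search(q, m, k = 15, metric = metric)
    want <- oracle_knn(q, m, 15, metric)
    expect_equal(got$label, want$label)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
  }
  # self-match first at distance zero
  got <- knn_search(m[7, ], m, k = 3)
  expect_equal(got$label[1], rownames(m)[7])
  expect_equal(got$distance[1], 0)
  # ties break lexicographically
  tied <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE,
                 dimnames = list(c("ZZ", "MM", "AA"), NULL))
  got_t <- knn_search(c(0, 0), tied, k = 3)
  expect_equal(got_t$label, c("AA", "MM", "ZZ"))
  # k beyond the space returns everything
  expect_equal(nrow(knn_search(q, m, k = 1000)), 200L)
  expect_error(knn_search(q, m[0, , drop = FALSE]), "empty")
  expect_error(knn_search(rnorm(5), m), "does not match")
})

test_that("NJ handles the 2-leaf base case and the 3-leaf closed form", {
  d2 <- matrix(c(0, 7, 7, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(d2)
  expect_setequal(t2$tip.label, c("A", "B"))
  expect_equal(sum(t2$edge.length), 7)

  d3 <- matrix(c(0, 2, 4,
                 2, 0, 4,
                 4, 4, 0), 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(d3)
  pend <- setNames(t3$edge.length[t3$edge[, 2] <= 3], t3$tip.label[t3$edge[t3$edge[, 2] <= 3, 2]])
  expect_equal(pend[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("NJ exactly reconstructs additive distance matrices", {
  skip_if_not_installed("phangorn")
  set.seed(63)
  for (rep in 1:5) {
    true <- ape::rtree(8)
    true$edge.length <- runif(nrow(true$edge), 0.5, 2)
    D <- ape::cophenetic.phylo(true)
    rec <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(ape::unroot(true), ape::unroot(rec)), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)] - D)), 1e-8)
  }
})

test_that("invalid distance matrices are rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(bad), "not symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(neg), "negative")
  expect_error(neighbor_joining(matrix(0, 1, 1)), "at least 2")
})

test_that("Newick output quotes expression labels and round-trips", {
  d2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  s <- write_newick(neighbor_joining(d2))
  expect_match(s, "^\\(A:1,B:1\\);$")

  labs <- c("{ALPHA | BETA} & GAMMA", "_CARDI & VASCUL", "PLAIN", "TWO WORDS")
  set.seed(64)
  m <- matrix(rnorm(4 * 5), 4, 5, dimnames = list(labs, NULL))
  tr <- neighbor_joining(distance_matrix(m))
  back <- read_newick(text = write_newick(tr))
  expect_setequal(back$tip.label, labs)

  skip_if_not_installed("phangorn")
  for (rep in 1:5) {
    t0 <- ape::rtree(20)
    rt <- read_newick(text = write_newick(t0))
    expect_equal(phangorn::RF.dist(ape::unroot(t0), ape::unroot(rt)), 0)
    expect_equal(sum(rt$edge.length), sum(t0$edge.length), tolerance = 1e-8)
  }
})

test_that("rooting at a leaf preserves the unrooted topology", {
  skip_if_not_installed("phangorn")
  fit <- fixture_fit()
  sp <- fit$tm$wwrd[1:10, ]
  tr <- embedding_tree(sp)
  rooted <- root_at_leaf(tr, rownames(sp)[3])
  expect_true(ape::is.rooted(rooted))
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(rooted)), 0)
  expect_error(root_at_leaf(tr, "NOT A LEAF"), "not in tree")
})
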