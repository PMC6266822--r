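mknet <- function(a, b, w, s = 0.5, provenance = "N") {
  coexpression_network(data.frame(gene_a = a, gene_b = b, weight = w,
                                  support = s),
                       provenance = provenance)
}

test_that("overlap keeps shared edges with matching sign only", {
  A <- mknet(c("g1", "g2"), c("g2", "g3"), c(0.8, -0.7), c(0.5, 0.75),
             provenance = "A")
  B <- mknet(c("g1", "g2"), c("g2", "g3"), c(0.9, 0.7), c(0.25, 1),
             provenance = "B")
  ov <- overlap_network(A, B)
  expect_equal(nrow(ov$edges), 1)
  expect_identical(ov$edges$gene_a, "g1")
  expect_equal(ov$edges$weight, 0.85)
  expect_equal(ov$edges$support, 0.25)       # min of parent supports
  expect_identical(ov$nodes, c("g1", "g2"))  # incident genes only
  expect_identical(ov$provenance, "overlap(A,B)")
})

test_that("overlap is idempotent, commutative and a subset of parents", {
  set.seed(51)
  rand_net <- function(p) {
    pairs <- t(utils::combn(sprintf("g%02d", 1:8), 2))
    keep <- sample(nrow(pairs), 12)
    mknet(pairs[keep, 1], pairs[keep, 2],
          w = stats::runif(12, -1, 1) * 0.99 + 0.005)
  }
  A <- rand_net(); B <- rand_net(); C <- rand_net()
  expect_identical(edge_keys(overlap_network(A, A)), edge_keys(A))
  expect_identical(edge_keys(overlap_network(A, B)),
                   edge_keys(overlap_network(B, A)))
  ab <- overlap_network(A, B)
  expect_true(all(edge_keys(ab) %in% edge_keys(A)))
  expect_true(all(edge_keys(ab) %in% edge_keys(B)))
  expect_identical(edge_keys(overlap_network(ab, C)),
                   edge_keys(overlap_network(A, overlap_network(B, C))))

  D1 <- mknet(c("a", "b"), c("b", "c"), c(0.9, 0.8))
  D2 <- mknet(c("x", "y"), c("y", "z"), c(0.9, 0.8))
  expect_equal(nrow(overlap_network(D1, D2)$edges), 0)
})

test_that("two cliques joined by a bridge split at the bridge", {
  cl1 <- t(utils::combn(c("a1", "a2", "a3", "a4"), 2))
  cl2 <- t(utils::combn(c("b1", "b2", "b3", "b4"), 2))
  edges <- rbind(cl1, cl2, c("a1", "b1"))
  net <- mknet(edges[, 1], edges[, 2], 0.9)

  # exhaustive oracle: the modularity-optimal 2-partition of the 8 nodes
  g <- as_igraph(net)
  nodes <- igraph::V(g)$name
  best <- NULL; best_q <- -Inf
  for (mask in 0:(2^7 - 1)) {  # fix node 1's side; enumerate the rest
    part <- c(1L, as.integer(intToBits(mask))[1:7] + 1L)
    q <- igraph::modularity(g, part)
    if (q > best_q) { best_q <- q; best <- part }
  }
  expect_setequal(nodes[best == best[1]], c("a1", "a2", "a3", "a4"))

  cl <- community_cluster(net, min_cluster_size = 3, seed = 9L)
  expect_equal(sort(unname(attr(cl, "sizes"))), c(4L, 4L))
  got_a <- cl$cluster[match(c("a1", "a2", "a3", "a4"), cl$gene)]
  got_b <- cl$cluster[match(c("b1", "b2", "b3", "b4"), cl$gene)]
  expect_length(unique(got_a), 1)
  expect_length(unique(got_b), 1)
  expect_false(unique(got_a) == unique(got_b))
})

test_that("small components stay unclustered and cliques stay whole", {
  cl5 <- t(utils::combn(sprintf("c%d", 1:5), 2))
  edges <- rbind(cl5, c("p1", "p2"))   # a 5-clique plus a lone pair
  net <- mknet(edges[, 1], edges[, 2], 0.8)
  cl <- community_cluster(net, min_cluster_size = 3, seed = 1L)
  expect_identical(cl$cluster[match(c("p1", "p2"), cl$gene)],
                   c("unclustered", "unclustered"))
  expect_identical(unique(cl$cluster[match(sprintf("c%d", 1:5),
                                           cl$gene)]), "1")
  expect_identical(unname(attr(cl, "sizes")[]), 5L)

  # empty network -> empty assignment
  empty <- community_cluster(coexpression_network(NULL))
  expect_equal(nrow(empty), 0)
})

test_that("clustering is a deterministic partition of the node set", {
  set.seed(52)
  pairs <- t(utils::combn(sprintf("g%02d", 1:15), 2))
  keep <- sample(nrow(pairs), 40)
  net <- mknet(pairs[keep, 1], pairs[keep, 2],
               stats::runif(40, 0.6, 1))
  cl1 <- community_cluster(net, min_cluster_size = 3, seed = 5L)
  cl2 <- community_cluster(net, min_cluster_size = 3, seed = 5L)
  expect_identical(cl1, cl2)
  expect_setequal(cl1$gene, net$nodes)
  expect_identical(anyDuplicated(cl1$gene), 0L)
  sizes <- table(cl1$cluster[cl1$cluster != "unclustered"])
  expect_true(all(sizes >= 3))
  # dense ids ordered by decreasing size
  ids <- as.integer(names(attr(cl1, "sizes")))
  expect_identical(ids, seq_along(ids))
  expect_true(all(diff(as.integer(attr(cl1, "sizes"))) <= 0))
})

test_that("degree reports count incident edges", {
  star <- mknet(rep("hub", 4), sprintf("leaf%d", 1:4), 0.9)
  deg <- degree_report(star)
  expect_equal(deg[["hub"]], 4L)
  expect_true(all(deg[sprintf("leaf%d", 1:4)] == 1L))
  expect_identical(names(deg)[1], "hub")

  expect_length(degree_report(coexpression_network(NULL)), 0)

  tri <- mknet(c("a", "a", "b"), c("b", "c", "c"), 0.9)
  expect_true(all(degree_report(tri) == 2L))
})

test_that("hypergeometric enrichment matches exact tail summation", {
  coll <- structure(list(
    S1 = list(description = "d", genes = c("g1", "g2", "g3")),
    S2 = list(description = "d", genes = c("g4", "g9")),
    S3 = list(description = "d", genes = c("g5", "g6", "g7", "g8"))),
    class = "gene_set_collection")
  universe <- sprintf("g%d", 1:10)

  # complete overlap: N=10, K=3, n=3, k=3 -> p = 1/C(10,3)
  res <- ora(c("g1", "g2", "g3"), universe, coll, min_overlap = 2,
             p_threshold = 0.01)
  expect_equal(res$p_value[res$set_name == "S1"], 1 / 120,
               tolerance = 1e-12)

  # k = 1 rows are excluded by the overlap gate regardless of p
  res <- ora(c("g4", "g1"), universe, coll, min_overlap = 2,
             p_threshold = 1)
  expect_false("S2" %in% res$set_name)

  # k = 0 has p = 1 and is excluded
  res <- ora(c("g9", "g10"), universe, coll, min_overlap = 0,
             p_threshold = 1, min_genes = 0)
  expect_equal(res$p_value[res$set_name == "S3"], 1)

  expect_error(ora("absent", universe, coll), "absent from universe")

  set.seed(53)
  for (i in 1:30) {
    N <- sample(10:50, 1)
    universe <- sprintf("u%02d", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    S <- sample(universe, K); query <- sample(universe, n)
    coll2 <- structure(list(S = list(description = "", genes = S)),
                       class = "gene_set_collection")
    res <- ora(query, universe, coll2, min_overlap = 0, p_threshold = 1)
    k <- length(intersect(S, query))
    expect_equal(res$p_value, reference_hyper_tail(k, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("the number-or-percentage gate keeps either route open", {
  coll <- structure(list(
    big = list(description = "", genes = sprintf("u%02d", 1:20)),
    small = list(description = "", genes = c("u01", "u02"))),
    class = "gene_set_collection")
  universe <- sprintf("u%02d", 1:40)
  query <- c("u01", "u02")
  # k = 2 for both sets; min_genes = 3 blocks both unless the percentage
  # route (2/2 = 100% for "small") lets it through
  res <- ora(query, universe, coll, min_overlap = 2, p_threshold = 1,
             min_genes = 3, min_fraction = 0.5)
  expect_true("small" %in% res$set_name)
  expect_false("big" %in% res$set_name)
})

test_that("adjusted Rand agrees with an independent implementation", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               1)
  skip_if_not_installed("mclust")
  set.seed(54)
  for (i in 1:20) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})
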