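test_that("within-individual Pearson correlations match closed forms", {
  st <- make_study(list(G = list(
    I1 = list(x = c(1, 2, 3), y = c(6, 4, 2), z = c(5, 5, 5),
              w = c(1, 2, 10)))))
  stack <- individual_correlations(st, c("x", "y", "z", "w"), "G")
  m <- stack$matrices$I1
  expect_equal(m["x", "y"], -1)
  expect_true(is.na(m["x", "z"]))                 # zero variance
  expect_equal(m["x", "w"], 9 / (sqrt(2) * sqrt(438 / 9)),
               tolerance = 1e-12)
  expect_equal(m["x", "w"], 0.9122, tolerance = 1e-4)
  expect_identical(m, t(m))
  expect_equal(diag(m)[c("x", "y", "w")], c(x = 1, y = 1, w = 1))
})

test_that("incomplete series and degenerate gene sets are rejected", {
  st <- make_study(list(G = list(I1 = list(x = 1:3, y = 3:1),
                                 I2 = list(x = 1:3, y = 3:1))))
  expect_error(individual_correlations(st, "x", "G"), "at least 2 genes")
  # drop one sample of I2 -> incomplete time series
  st2 <- subset_study(st, samples = setdiff(st$samples$sample_id,
                                            "I2_T3"))
  expect_error(individual_correlations(st2, c("x", "y"), "G"),
               "incomplete time series")
})

test_that("the edge rule applies cutoff, support and sign consistency", {
  params <- network_params(corr_cutoff = 0.6, support_fraction = 0.25)

  net <- build_network(pair_stack(c(0.9, 0.65, 0.1, -0.3)), params)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, mean(c(0.9, 0.65)))
  expect_equal(net$edges$support, 0.5)
  expect_identical(net$edges$sign, "+")

  # no individual passes the cutoff
  net <- build_network(pair_stack(rep(0.5, 4)), params)
  expect_equal(nrow(net$edges), 0)

  # qualifying correlations with conflicting signs
  net <- build_network(pair_stack(c(0.9, -0.9, 0, 0)), params)
  expect_equal(nrow(net$edges), 0)

  # undefined correlations count against support, not for it
  net <- build_network(pair_stack(c(0.9, NA, NA, NA),
                                  n_genes = 2), params)
  expect_equal(net$edges$support, 0.25)
  # mean over all defined individuals as the configurable alternative
  net <- build_network(pair_stack(c(0.9, 0.7, 0.1, NA)), params,
                       weight_over = "all")
  expect_equal(net$edges$weight, mean(c(0.9, 0.7, 0.1)))
})

test_that("vectorised network construction equals the loop reference", {
  set.seed(41)
  for (rep in 1:20) {
    stack <- random_stack(n_genes = sample(3:12, 1),
                          n_ind = sample(2:8, 1),
                          constant_gene = rep %% 4 == 0)
    cutoff <- stats::runif(1, 0.3, 0.8)
    frac <- stats::runif(1, 0.1, 0.6)
    got <- build_network(stack, network_params(cutoff, frac))$edges
    want <- reference_network_edges(stack, cutoff, frac)
    expect_equal(got[, c("gene_a", "gene_b")],
                 want[, c("gene_a", "gene_b")],
                 ignore_attr = TRUE)
    expect_equal(got$weight, want$weight, tolerance = 1e-12)
    expect_equal(got$support, want$support, tolerance = 1e-12)
  }
})

test_that("tightening thresholds nests the edge sets", {
  set.seed(43)
  stack <- random_stack(10, 8)
  # raising the support fraction can only remove edges
  base <- build_network(stack, network_params(0.4, 0.2))
  for (frac in c(0.3, 0.5, 0.8)) {
    tighter <- build_network(stack, network_params(0.4, frac))
    expect_true(all(edge_keys(tighter) %in% edge_keys(base)))
  }
  # raising the correlation cutoff can only remove edges when qualifier
  # signs cannot conflict (here: all correlations made positive); with
  # mixed signs a higher cutoff may drop a conflicting qualifier and
  # thereby legitimise a pair, so no global nesting is claimed
  abs_stack <- make_stack(stack$gene_ids,
                          lapply(stack$matrices, abs))
  base <- build_network(abs_stack, network_params(0.4, 0.2))
  for (cutoff in c(0.5, 0.7, 0.9)) {
    tighter <- build_network(abs_stack, network_params(cutoff, 0.2))
    expect_true(all(edge_keys(tighter) %in% edge_keys(base)))
  }
})

test_that("group mean correlation averages defined entries", {
  m1 <- matrix(c(1, 0.8, 0.8, 1), 2); m2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  stack <- make_stack(c("a", "b"), list(m1, m2))
  expect_equal(group_mean_correlation(stack)["a", "b"], 0.6)

  m3 <- matrix(c(1, NA, NA, 1), 2); m4 <- matrix(c(1, 0.5, 0.5, 1), 2)
  stack <- make_stack(c("a", "b"), list(m3, m4))
  expect_equal(group_mean_correlation(stack)["a", "b"], 0.5)

  single <- make_stack(c("a", "b"), list(m1))
  expect_equal(group_mean_correlation(single), m1, ignore_attr = TRUE)
})

test_that("Frobenius distance follows the double-sum definition", {
  A <- diag(2); B <- matrix(1, 2, 2)
  expect_equal(frobenius_distance(A, A), 0)
  expect_equal(frobenius_distance(A, B), sqrt(2))

  set.seed(44)
  for (i in 1:10) {
    A <- random_symmetric(6); B <- random_symmetric(6)
    expect_equal(frobenius_distance(A, B), reference_frobenius(A, B),
                 tolerance = 1e-12)
  }
  expect_error(frobenius_distance(diag(2), diag(3)), "mismatched")
  rownames(A) <- colnames(A) <- letters[1:6]
  B2 <- A; rownames(B2) <- colnames(B2) <- letters[7:12]
  expect_error(frobenius_distance(A, B2), "different gene sets")
})

test_that("Frobenius distance is a metric on defined matrices", {
  set.seed(45)
  for (i in 1:50) {
    A <- random_symmetric(5); B <- random_symmetric(5)
    C <- random_symmetric(5)
    dAB <- frobenius_distance(A, B)
    expect_gte(dAB, 0)
    expect_equal(dAB, frobenius_distance(B, A))
    expect_lte(frobenius_distance(A, C),
               dAB + frobenius_distance(B, C) + 1e-12)
  }
})

test_that("undefined entries are excluded pairwise or rejected", {
  A <- matrix(c(1, NA, NA, 1), 2); B <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(frobenius_distance(A, B), 0)  # only defined entries differ
  expect_error(frobenius_distance(A, B, na_action = "error"), "undefined")
})

test_that("distance profiles recompute per-individual Frobenius norms", {
  m <- matrix(c(1, 0.5, 0.5, 1), 2)
  stack <- make_stack(c("a", "b"), list(I1 = m, I2 = m, I3 = m))
  expect_equal(unname(individual_distance_profile(stack)), rep(0, 3))

  stack <- make_stack(c("a", "b"), list(I1 = m, I2 = -m + 2 * diag(2)))
  d <- individual_distance_profile(stack)
  expect_equal(d[["I1"]], d[["I2"]])  # symmetric about the mean

  set.seed(46)
  stack <- random_stack(6, 5)
  mu <- group_mean_correlation(stack)
  d <- individual_distance_profile(stack)
  expect_true(all(diff(d) <= 1e-15))  # sorted descending
  for (ind in names(stack$matrices))
    expect_equal(d[[ind]], reference_frobenius(stack$matrices[[ind]], mu),
                 tolerance = 1e-12)
  expect_error(individual_distance_profile(make_stack(c("a", "b"),
                                                      list(m))),
               "at least 2")
})
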