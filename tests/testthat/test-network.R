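test_that("index of association reproduces its closed-form endpoints", {
  expect_equal(index_of_association(c(5, 5), c(1, 1)), 100)
  expect_equal(index_of_association(c(10, 0), c(0, 10)), 0)
  expect_equal(index_of_association(c(3, 1), c(1, 1)), 75)
  set.seed(5)
  for (rep in 1:10) {
    x <- rpois(8, 4) + 1; y <- rpois(8, 4) + 1
    expect_equal(index_of_association(x, y), index_of_association(y, x))
    expect_equal(index_of_association(x, 3.7 * x), 100)
    ia <- index_of_association(x, y)
    expect_true(ia >= 0 && ia <= 100)
  }
  expect_error(index_of_association(c(0, 0), c(1, 1)), "undefined IA")
})

test_that("the IA matrix agrees with elementwise computation", {
  set.seed(8)
  tb <- matrix(rpois(24, 5) + 1, 4, 6)
  rownames(tb) <- letters[1:4]
  M <- ia_matrix(tb)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(M[i, j], index_of_association(tb[i, ], tb[j, ]))
  expect_equal(diag(M), setNames(rep(100, 4), letters[1:4]))
})

test_that("the permutation null is deterministic and honours both conventions", {
  # distinct site values: a site permutation virtually never reproduces the
  # observed perfect association
  prof <- c(55, 34, 21, 13, 8, 5, 3, 2, 27, 41, 17, 11, 7)
  tb <- rbind(a = prof, b = 2 * prof,
              c = c(2, 30, 2, 28, 2, 1, 5, 9, 4, 3, 2, 6, 1))
  n1 <- ia_null(tb, n_perm = 200, seed = 4)
  n2 <- ia_null(tb, n_perm = 200, seed = 4)
  expect_identical(n1, n2)
  # proportional pair: observed IA = 100 beats every permutation
  expect_equal(n1$ia["a", "b"], 100)
  expect_equal(n1$p["a", "b"], 0)
  add1 <- ia_null(tb, n_perm = 200, seed = 4, convention = "add-one")
  expect_equal(add1$p["a", "b"], 1 / 201)
})

test_that("graph construction applies IA, FDR and abundance filters", {
  prof <- c(55, 34, 21, 13, 8, 5, 3, 2, 27, 41, 17, 11, 7)
  tb <- rbind(a = prof, b = 2 * prof, c = 3 * prof,
              d = c(2, 30, 2, 28, 2, 1, 5, 9, 4, 3, 2, 6, 1),
              single = c(1, rep(0, 12)))
  null <- ia_null(tb, n_perm = 200, seed = 2)
  g <- build_graph(tb, null)
  expect_false("single" %in% igraph::V(g)$name)  # abundance < 2 excluded
  sub <- igraph::induced_subgraph(g, c("a", "b", "c"))
  expect_equal(igraph::ecount(sub), 3)           # proportional triple -> triangle
  # no pair passes -> edgeless graph keeps eligible nodes
  g2 <- build_graph(tb, null, ia_min = 100.1)
  expect_equal(igraph::ecount(g2), 0)
  expect_equal(igraph::vcount(g2), 4)
})

test_that("network statistics match closed forms on canonical graphs", {
  k4 <- igraph::make_full_graph(4)
  s <- network_stats(k4)
  expect_equal(s$density, 1)
  expect_equal(s$mean_neighbors, 3)
  expect_equal(s$centralization, 0)
  expect_equal(s$clustering_coefficient, 1)
  star <- igraph::make_star(5, mode = "undirected")
  s2 <- network_stats(star)
  expect_equal(s2$density, 0.4)
  expect_equal(s2$centralization, 1.0)
  expect_equal(s2$clustering_coefficient, 0)
  expect_equal(s2$heterogeneity, sd(c(4, 1, 1, 1, 1)) / mean(c(4, 1, 1, 1, 1)))
  tri2 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                 igraph::make_full_graph(3))
  s3 <- network_stats(tri2)
  expect_equal(s3$n_components, 2)
  expect_equal(s3$clustering_coefficient, 1)
  expect_equal(sum(igraph::degree(tri2)), 2 * s3$n_edges)
  expect_true(is.na(network_stats(igraph::make_full_graph(2))$centralization))
})

test_that("edge-weight rescaling maps [85,100] linearly onto [0.001,0.15]", {
  expect_equal(rescale_edge_weights(85), 0.001)
  expect_equal(rescale_edge_weights(100), 0.15)
  expect_equal(rescale_edge_weights(92.5), 0.0755)
  expect_error(rescale_edge_weights(80), "outside")
})

test_that("MCL recovers disconnected components and planted blocks", {
  tri2 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                 igraph::make_full_graph(3))
  igraph::E(tri2)$weight <- 0.1
  res <- mcl(tri2)
  expect_equal(res$n_clusters, 2)
  expect_true(same_partition(unname(res$membership), rep(1:2, each = 3)))
  single <- igraph::make_empty_graph(1, directed = FALSE)
  expect_equal(mcl(single)$n_clusters, 1)
  # 4 planted dense blocks of 5 nodes with weak inter-block edges
  set.seed(33)
  W <- matrix(0, 20, 20)
  truth <- rep(1:4, each = 5)
  for (i in 1:19) for (j in (i + 1):20) {
    w <- if (truth[i] == truth[j]) runif(1, 0.08, 0.15) else
      if (runif(1) < 0.15) runif(1, 0.001, 0.004) else 0
    W[i, j] <- W[j, i] <- w
  }
  res2 <- mcl(W)
  expect_equal(res2$n_clusters, 4)
  expect_true(same_partition(unname(res2$membership), truth))
  # agreement with the independent reference iteration
  ref <- reference_mcl(W)
  expect_true(same_partition(unname(res2$membership), ref))
  # output is a partition covering all nodes
  expect_length(res2$membership, 20)
  expect_false(anyNA(res2$membership))
})

test_that("cluster summaries report size, abundance and taxon richness", {
  memb <- c(a = 1L, b = 1L, c = 1L, d = 2L)
  meta <- data.frame(node = letters[1:4], abundance = c(10, 20, 30, 5),
                     phylum = c("P1", "P1", "P2", "P3"),
                     class = c("C1", "C2", "C3", "C4"))
  out <- cluster_summary(memb, meta)
  expect_equal(out$size, c(3, 1))
  expect_equal(out$n_phyla[1], 2)
  expect_equal(out$n_classes[1], 3)
  expect_equal(out$mean_abundance[1], 20)
  expect_equal(out$max_abundance[1], 30)
  empty <- cluster_summary(integer(0), meta)
  expect_equal(nrow(empty), 0)
})

test_that("guild of proportional oligotypes forms one connected component", {
  set.seed(55)
  base <- c(50, 1, 1, 30, 1, 1, 20, 1, 1, 10, 1, 1, 5)
  guild <- t(sapply(1:5, function(i) rpois(13, i * base / 2) + (base > 5)))
  noise <- matrix(rpois(45 * 13, 6), 45, 13)
  tb <- rbind(guild, noise)
  rownames(tb) <- paste0("o", 1:50)
  null <- ia_null(tb, n_perm = 400, seed = 9)
  g <- build_graph(tb, null)
  comp <- igraph::components(g)
  expect_equal(length(unique(comp$membership[paste0("o", 1:5)])), 1)
})
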