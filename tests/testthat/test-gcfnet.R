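edge_df <- function(a, b, d) data.frame(a = a, b = b, distance = d,
                                        stringsAsFactors = FALSE)

test_that("the network cutoff is inclusive at 0.5 and isolated nodes are retained", {
  net <- build_network(edge_df("A", "B", 0.50), cutoff = 0.5)
  expect_equal(nrow(net$edges), 1L)
  net2 <- build_network(edge_df("A", "B", 0.51), cutoff = 0.5)
  expect_equal(nrow(net2$edges), 0L)
  expect_setequal(net2$nodes, c("A", "B"))

  net3 <- build_network(edge_df(character(), character(), numeric()),
                        nodes = c("A", "B", "C"))
  fams <- connected_components(net3)
  expect_equal(length(unique(fams$family_id)), 3L)

  expect_error(build_network(edge_df("A", "D", 0.2), nodes = c("A", "B")),
               "absent from node list")
  expect_error(build_network(edge_df("A", "B", 0.2), cutoff = 1.2), "cutoff")
})

test_that("families are connected components with deterministic, order-invariant labels", {
  edges <- edge_df(c("A", "B"), c("B", "C"), c(0.1, 0.2))
  net <- build_network(edges, nodes = c("A", "B", "C", "D"))
  mem <- connected_components(net)
  expect_equal(mem$family_id[mem$bgc_id == "C"], "A")
  expect_equal(mem$family_id[mem$bgc_id == "D"], "D")

  # complete graph on 4 nodes -> one family
  cg <- t(combn(c("N1", "N2", "N3", "N4"), 2))
  one <- connected_components(build_network(edge_df(cg[, 1], cg[, 2],
                                                    rep(0.1, 6))))
  expect_equal(length(unique(one$family_id)), 1L)

  # shuffled edge and node order leaves the partition unchanged
  set.seed(1)
  shuf <- edges[sample(nrow(edges)), c("a", "b", "distance")]
  tmp <- shuf$a[1]; shuf$a[1] <- shuf$b[1]; shuf$b[1] <- tmp
  mem2 <- connected_components(build_network(shuf, nodes = c("D", "C", "B", "A")))
  expect_identical(mem[order(mem$bgc_id), ], mem2[order(mem2$bgc_id), ])
})

test_that("components match the transitive-closure oracle on a random graph", {
  set.seed(7)
  nodes <- sprintf("N%02d", 1:50)
  edges <- edge_df(sample(nodes, 60, TRUE), sample(nodes, 60, TRUE),
                   runif(60, 0, 0.5))
  edges <- edges[edges$a != edges$b, ]
  net <- build_network(edges, nodes = nodes)
  mem <- connected_components(net)
  expected <- oracle_components(nodes, net$edges)
  got <- split(mem$bgc_id, mem$family_id)
  expect_identical(partition_signature(mem$bgc_id, mem$family_id),
                   paste(sort(vapply(expected, function(g)
                     paste(sort(g), collapse = ","), "")), collapse = ";"))
})

test_that("families with at least one reference member are known, others novel, monotonically", {
  edges <- edge_df(c("A", "B", "X"), c("B", "BGC0000001", "Y"),
                   c(0.2, 0.3, 0.1))
  net <- build_network(edges, nodes = c("A", "B", "BGC0000001", "X", "Y", "D"))
  mem <- connected_components(net)
  fams <- classify_novelty(mem, "BGC0000001")
  known <- fams$is_known[fams$family_id == "A"]
  expect_true(known)
  expect_false(fams$is_known[fams$family_id == "D"])
  expect_equal(novel_fraction(fams), 2 / 3)

  # adding a reference to a family never flips known -> novel
  fams2 <- classify_novelty(mem, c("BGC0000001", "D"))
  expect_true(all(fams2$is_known >= fams$is_known))

  # all nodes reference -> nothing novel
  all_ref <- classify_novelty(mem, mem$bgc_id)
  expect_equal(novel_fraction(all_ref), 0)
})

test_that("distance to the closest reference uses direct retained edges with a 0.51 sentinel", {
  ref <- "BGC0000001"
  edges <- edge_df(c("A", "A", "B", "C"),
                   c(ref, "B", ref, "B"),
                   c(0.30, 0.10, 0.45, 0.20))
  net <- build_network(edges, nodes = c("A", "B", "C", "D", ref))
  sc <- min_reference_distance(net)
  score <- setNames(sc$distance_to_reference, sc$bgc_id)
  expect_equal(score[["A"]], 0.30) # min of direct edges 0.30 < via B
  expect_equal(score[["B"]], 0.45)
  # C sits in the known family but has no direct edge to the reference
  expect_equal(score[["C"]], 0.51)
  expect_equal(score[["D"]], 0.51) # unconnected singleton
  expect_false(ref %in% sc$bgc_id)
  expect_true(all(sc$distance_to_reference <= 0.51))
  expect_error(min_reference_distance(net, sentinel = 0.4), "sentinel")
})

test_that("per-sample minimum novelty takes the class-wise minimum and omits absent samples", {
  scores <- data.frame(bgc_id = c("G1", "G2", "G3", "G4"),
                       distance_to_reference = c(0.51, 0.22, 0.40, 0.51))
  inv <- data.frame(bgc_id = c("G1", "G2", "G3", "G4"),
                    sample_id = c("S1", "S1", "S1", "S2"),
                    bgc_class = c("NRPS", "NRPS", "NRPS", "NRPS"))
  out <- sample_min_novelty(scores, inv, "NRPS")
  expect_equal(out$min_novelty[out$sample_id == "S1"], 0.22)
  expect_equal(out$min_novelty[out$sample_id == "S2"], 0.51)
  terp <- sample_min_novelty(scores, inv, "terpene")
  expect_equal(nrow(terp), 0L)
})

test_that("greedy modularity matches the exhaustive partition oracle on two bridged cliques", {
  cl1 <- t(combn(c("a1", "a2", "a3", "a4"), 2))
  cl2 <- t(combn(c("b1", "b2", "b3", "b4"), 2))
  edges <- edge_df(c(cl1[, 1], cl2[, 1], "a1"), c(cl1[, 2], cl2[, 2], "b1"),
                   rep(0.1, 13))
  net <- build_network(edges)
  res <- modularity_communities(net)
  expect_equal(length(unique(res$membership$community)), 2L)
  expect_gt(res$modularity, 0)
  best <- oracle_best_modularity(net$nodes, net$edges)
  expect_equal(res$modularity, best$modularity, tolerance = 1e-10)
  mem <- setNames(res$membership$community, res$membership$bgc_id)
  expect_identical(partition_signature(names(mem), mem),
                   partition_signature(names(best$membership),
                                       best$membership))

  # edgeless network: every node its own community, Q = 0
  lone <- build_network(edge_df(character(), character(), numeric()),
                        nodes = c("x", "y"))
  res0 <- modularity_communities(lone)
  expect_equal(res0$modularity, 0)
  expect_equal(length(unique(res0$membership$community)), 2L)
})

test_that("known-family fraction tracks the planted reference fraction binomially", {
  cfg <- sim_config(n_samples = 20, n_families_per_class = 40,
                    ref_fraction = 0.3, seed = 13)
  st <- simulate_study(cfg)
  truth <- st$truth$membership
  fams <- do.call(rbind, lapply(cfg$classes, function(cl) {
    nodes <- truth$bgc_id[truth$bgc_class == cl]
    if (!length(nodes)) return(NULL)
    net <- build_network(st$networks[[cl]], nodes = nodes)
    classify_novelty(connected_components(net),
                     nodes[is_reference_id(nodes)])
  }))
  n_known <- sum(fams$is_known)
  bounds <- qbinom(c(0.005, 0.995), nrow(fams), 0.3)
  expect_gte(n_known, bounds[1])
  expect_lte(n_known, bounds[2])
})
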