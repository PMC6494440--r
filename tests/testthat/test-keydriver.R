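chain_network <- function(...) {
  genes <- c(...)
  causal_network(data.frame(from = genes[-length(genes)], to = genes[-1],
                            cohort = "chain"))
}

test_that("network construction rejects self-loops and merges duplicates", {
  expect_error(causal_network(data.frame(from = "a", to = "a")), "self-loop")
  g <- causal_network(data.frame(from = c("a", "a"), to = c("b", "b"),
                                 cohort = c("c1", "c2")))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$cohort, "c1,c2")
})

test_that("union of networks is idempotent, commutative, and tag-merging", {
  g1 <- causal_network(data.frame(from = "a", to = "b", cohort = "c1"),
                       name = "g1")
  g2 <- causal_network(data.frame(from = c("a", "b"), to = c("b", "c"),
                                  cohort = "c2"), name = "g2")
  self <- union_network(list(g1, g1))
  expect_equal(self$edges[, c("from", "to")], g1$edges[, c("from", "to")])
  u12 <- union_network(list(g1, g2))
  u21 <- union_network(list(g2, g1))
  expect_equal(u12$edges, u21$edges)
  expect_equal(nrow(u12$edges), 2)
  ab <- u12$edges[u12$edges$from == "a" & u12$edges$to == "b", ]
  expect_equal(ab$cohort, "c1,c2")
  # disjoint edge sets add
  g3 <- causal_network(data.frame(from = "x", to = "y", cohort = "c3"))
  expect_equal(nrow(union_network(list(g1, g3))$edges), 2)
  # opposite arcs from different cohorts are both retained
  g4 <- causal_network(data.frame(from = "b", to = "a", cohort = "c4"))
  expect_equal(nrow(union_network(list(g1, g4))$edges), 2)
})

test_that("a directed chain yields singleton layers", {
  net <- chain_network("a", "b", "c", "d")
  nb <- downstream_layers(net, "a", max_depth = 3)
  expect_equal(nb$layers, list("b", "c", "d"))
  # a terminal seed has all-empty layers
  nb2 <- downstream_layers(net, "d", max_depth = 3)
  expect_equal(lengths(nb2$layers), c(0L, 0L, 0L))
  expect_error(downstream_layers(net, "nope"), "not in network")
})

test_that("cycles cause no revisit and the seed joins no layer", {
  net <- causal_network(data.frame(from = c("a", "b", "c"),
                                   to = c("b", "c", "a")))
  nb <- downstream_layers(net, "a", max_depth = 5)
  expect_equal(nb$layers[[1]], "b")
  expect_equal(nb$layers[[2]], "c")
  expect_true(all(lengths(nb$layers[3:5]) == 0))
  expect_false("a" %in% unlist(nb$layers))
})

test_that("BFS layers equal shortest-path distances on random digraphs", {
  set.seed(202)
  for (i in 1:60) {
    edges <- random_digraph(10, p_edge = runif(1, 0.05, 0.3))
    if (nrow(edges) == 0) next
    net <- causal_network(edges)
    seed <- sample(net$nodes, 1)
    nb <- downstream_layers(net, seed, max_depth = 9)
    dist <- shortest_dist_oracle(net$nodes, net$edges, seed)
    for (d in seq_along(nb$layers)) {
      expect_setequal(nb$layers[[d]],
                      names(dist)[is.finite(dist) & dist == d])
    }
  }
})

test_that("layering is invariant to edge-list order", {
  set.seed(31)
  edges <- random_digraph(12, 0.2)
  net1 <- causal_network(edges)
  net2 <- causal_network(edges[sample(nrow(edges)), ])
  seed <- net1$nodes[1]
  expect_equal(downstream_layers(net1, seed, 6)$layers,
               downstream_layers(net2, seed, 6)$layers)
})

test_that("layer enrichment matches enumeration on a tiny instance", {
  # universe of 8, one layer of 3, signature of 4, overlap 2
  uni <- paste0("g", 1:8)
  net <- causal_network(data.frame(from = "g1", to = c("g2", "g3", "g4")))
  nb <- downstream_layers(net, "g1", max_depth = 2)
  sig <- c("g2", "g3", "g5", "g6")
  tab <- layer_enrichment(nb, sig, uni)
  expect_equal(tab$overlap[1], 2)
  expect_equal(tab$p[1], enum_hypergeom_tail(2, 3, 4, 8), tolerance = 1e-12)
  # an empty layer scores overlap 0 at p = 1
  expect_equal(tab$overlap[2], 0)
  expect_equal(tab$p[2], 1)
})

test_that("cumulative layer enrichment equals enrichment of layer unions", {
  sim <- simulate_causal_network(simulation_config(seed = 9))
  nb <- downstream_layers(sim$network, sim$truth$planted_driver, 4)
  uni <- sim$network$nodes
  sig <- sim$truth$planted_in_network
  cum <- layer_enrichment(nb, sig, uni, cumulative = TRUE)
  for (k in 1:4) {
    direct <- overlap_enrichment(
      intersect(unique(unlist(nb$layers[1:k])), uni), intersect(sig, uni),
      uni)
    expect_equal(cum$p[k], direct$p_value)
    expect_equal(cum$overlap[k], direct$overlap)
  }
})

test_that("the planted driver ranks first on the default simulation", {
  sim <- simulate_causal_network(simulation_config(seed = 3))
  rk <- rank_key_drivers(sim$network, sim$truth$planted_in_network)
  expect_equal(rk$gene[1], sim$truth$planted_driver)
  expect_equal(rk$rank, seq_len(nrow(rk)))
  # nodes without outgoing edges are not candidates
  sinks <- setdiff(sim$network$nodes, sim$network$edges$from)
  expect_length(intersect(rk$gene, sinks), 0)
})

test_that("an uninformative whole-universe signature falls back to size", {
  net <- causal_network(data.frame(
    from = c("a", "a", "b", "c"), to = c("b", "c", "d", "e")))
  rk <- rank_key_drivers(net, net$nodes, max_depth = 3)
  expect_true(all(rk$p == 1))
  expect_true(all(rk$fold_enrichment == 1))
  expect_false(is.unsorted(-rk$neighborhood_size))
  expect_equal(rk$gene[1], "a")
})
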