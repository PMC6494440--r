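test_that("adjacency is |correlation|^beta with unit diagonal", {
  x <- rbind(g1 = c(1, 2, 3, 4, 5),
             g2 = c(2, 4, 6, 8, 10),     # perfectly correlated with g1
             g3 = c(5, 4, 3, 2, 1),      # perfectly anticorrelated
             g4 = c(1, 3, 2, 5, 4),
             g5 = c(2, 2, 1, 3, 9))
  a <- correlation_adjacency(x, beta = 6)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(a["g1", "g3"], 1)  # unsigned network
  expect_equal(unname(diag(a)), rep(1, 5))
  expect_equal(a["g4", "g5"], abs(cor(x["g4", ], x["g5", ]))^6,
               tolerance = 1e-10)
  expect_equal(a, t(a))
  xx <- rbind(x, flat = rep(2, 5))
  expect_error(correlation_adjacency(xx), "flat")
})

test_that("topological overlap matches the formula computed by hand", {
  a <- matrix(c(1.0, 0.8, 0.3, 0.0,
                0.8, 1.0, 0.5, 0.1,
                0.3, 0.5, 1.0, 0.6,
                0.0, 0.1, 0.6, 1.0), 4, 4)
  tom <- topological_overlap(a)
  # hand: l_12 = a13*a32 + a14*a42 = .3*.5 + 0*.1 = .15
  # k1 = 1.1, k2 = 1.4; TOM12 = (.15 + .8)/(min(1.1,1.4) + 1 - .8) = .95/1.3
  expect_equal(tom[1, 2], 0.95 / 1.3, tolerance = 1e-12)
  # l_34 = a31*a14 + a32*a24 = 0 + .05; k3 = 1.4, k4 = .7
  expect_equal(tom[3, 4], (0.05 + 0.6) / (0.7 + 1 - 0.6), tolerance = 1e-12)
  expect_equal(unname(diag(tom)), rep(1, 4))
  expect_equal(tom, t(tom))
  expect_error(topological_overlap(a * 2), "\\[0, 1\\]")
})

test_that("TOM of a 2-gene network is the adjacency, identical rows give 1", {
  a2 <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  expect_equal(topological_overlap(a2)[1, 2], 0.4)
  # two fully linked genes sharing every neighbor overlap completely
  a <- matrix(0, 5, 5)
  a[1, ] <- a[, 1] <- 1
  a[2, ] <- a[, 2] <- 1
  diag(a) <- 1
  tom <- topological_overlap(a)
  expect_equal(tom[1, 2], 1, tolerance = 1e-12)
})

test_that("TOM stays within [0, 1] on random valid adjacencies", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    r <- matrix(runif(n * n), n, n)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    tom <- topological_overlap(a)
    expect_true(all(tom >= 0 - 1e-12 & tom <= 1 + 1e-12))
  }
})

test_that("module detection recovers planted blocks and honours min_size", {
  blk <- function(n, v) matrix(v, n, n)
  tom <- rbind(cbind(blk(10, 0.8), blk(10, 0.05)),
               cbind(blk(10, 0.05), blk(10, 0.8)))
  diag(tom) <- 1
  rownames(tom) <- colnames(tom) <- paste0("g", 1:20)
  part <- detect_modules(tom, min_size = 5, cut_height = 0.5)
  expect_equal(sort(unique(part$labels)), c("M1", "M2"))
  expect_equal(length(unique(part$labels[1:10])), 1)
  expect_equal(length(unique(part$labels[11:20])), 1)
  # a single uniform block is one module
  one <- detect_modules(blk(12, 0.9) + diag(0.1, 12), min_size = 5,
                        cut_height = 0.5)
  expect_equal(unname(unique(one$labels)), "M1")
  # min_size larger than every cluster leaves everything unassigned
  none <- detect_modules(tom, min_size = 11, cut_height = 0.5)
  expect_true(all(none$labels == "unassigned"))
})

test_that("module detection is invariant to gene order up to relabelling", {
  sim <- simulate_coexpression(simulation_config(seed = 2))
  tom <- topological_overlap(correlation_adjacency(sim$expression))
  p1 <- detect_modules(tom)
  o <- sample(nrow(tom))
  p2 <- detect_modules(tom[o, o])
  common <- names(p1$labels)
  tab <- table(p1$labels[common], p2$labels[common])
  # permutation-equivalent labelings: one nonzero cell per row and column
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("module-signature enrichment ranks the matching module first", {
  sim <- simulate_coexpression(simulation_config(seed = 5))
  tom <- topological_overlap(correlation_adjacency(sim$expression))
  part <- detect_modules(tom)
  sig <- names(sim$truth)[sim$truth == "module_2"]
  tab <- module_enrichment(part, sig)
  best <- names(which.max(table(part$labels[sig])))
  expect_equal(tab$module[1], best)
  expect_lt(tab$adjusted_p[1], 1e-20)
  # a signature disjoint from all modules scores p = 1 everywhere
  bg <- names(sim$truth)[sim$truth == "background"][1:30]
  flat <- module_enrichment(part, bg)
  expect_true(all(flat$p > 0.2))
  # a signature equal to one module attains the family minimum
  m1 <- names(part$labels)[part$labels == "M1"]
  exact <- module_enrichment(part, m1)
  expect_equal(exact$module[1], "M1")
})

test_that("zero factor loadings leave no detectable module structure", {
  cfg <- simulation_config(seed = 6, loading_range = c(0, 0))
  sim <- simulate_coexpression(cfg)
  tom <- topological_overlap(correlation_adjacency(sim$expression))
  part <- detect_modules(tom)
  expect_true(all(part$labels == "unassigned"))
})

test_that("recovered modules match the planted partition (ARI)", {
  sim <- simulate_coexpression(simulation_config(seed = 1))
  tom <- topological_overlap(correlation_adjacency(sim$expression))
  part <- detect_modules(tom)
  ari <- mclust::adjustedRandIndex(part$labels,
                                   sim$truth[names(part$labels)])
  expect_gte(ari, 0.8)
})
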