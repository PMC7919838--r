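test_that("modularity matches hand evaluation and the igraph cross-check", {
  tt <- two_triangles()
  part <- stats::setNames(c(1, 1, 1, 2, 2, 2), c("a", "b", "c", "d", "e", "f"))
  expect_equal(modularity_q(tt, part), 6 / 7 - 1 / 2, tolerance = 1e-12)
  # single community always scores zero
  expect_equal(modularity_q(tt, stats::setNames(rep(1, 6), names(part))), 0)
  # independent route: igraph's weighted modularity on random graphs
  set.seed(51)
  for (i in 1:10) {
    g <- random_connected_graph(sample(5:15, 1))
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.5, 3)
    memb <- sample(1:3, igraph::vcount(g), replace = TRUE)
    names(memb) <- igraph::V(g)$name
    expect_equal(modularity_q(g, memb),
                 igraph::modularity(g, memb[igraph::V(g)$name],
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("divisive clustering cuts the bridge between two cliques first", {
  tt <- two_triangles()
  gn <- girvan_newman(tt)
  expect_equal(gn$Q, 6 / 7 - 1 / 2, tolerance = 1e-12)
  a <- gn$assignment
  expect_equal(length(unique(a)), 2)
  expect_equal(length(unique(a[c("a", "b", "c")])), 1)
  expect_equal(length(unique(a[c("d", "e", "f")])), 1)
  expect_true(a["a"] != a["d"])
})

test_that("a complete graph stays one community with zero modularity", {
  k4 <- weighted_graph(edge_df("a","b","a","c","a","d","b","c","b","d","c","d"))
  gn <- girvan_newman(k4)
  expect_equal(length(unique(gn$assignment)), 1)
  expect_equal(gn$Q, 0)
})

test_that("divisive clustering never beats the exhaustive best partition", {
  set.seed(52)
  for (i in 1:12) {
    g <- random_connected_graph(sample(4:6, 1), p = 0.5)
    gn <- girvan_newman(g)
    expect_lte(gn$Q, best_partition_q(g) + 1e-12)
  }
})

test_that("girvan_newman is deterministic", {
  set.seed(53)
  g <- random_connected_graph(15, p = 0.25)
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.5, 2)
  expect_identical(girvan_newman(g)$assignment, girvan_newman(g)$assignment)
})

test_that("label propagation floods a star from its center seed", {
  st <- weighted_graph(edge_df("c","l1", "c","l2", "c","l3", "c","l4"))
  lp <- label_propagation(st, seeds = "c", rng_seed = 1)
  expect_equal(length(unique(lp$assignment)), 1)
})

test_that("two seeds in a barbell split it at the bridge", {
  bb <- weighted_graph(edge_df("a","b", "a","c", "b","c",
                               "d","e", "d","f", "e","f", "c","d"))
  lp <- label_propagation(bb, seeds = c("a", "f"), rng_seed = 2)
  expect_equal(length(unique(lp$assignment)), 2)
  expect_equal(length(unique(lp$assignment[c("a", "b", "c")])), 1)
  expect_equal(length(unique(lp$assignment[c("d", "e", "f")])), 1)
})

test_that("label propagation is reproducible under a fixed rng seed", {
  set.seed(54)
  g <- random_connected_graph(30, p = 0.15)
  seeds <- igraph::V(g)$name[1:3]
  expect_identical(label_propagation(g, seeds, rng_seed = 7)$assignment,
                   label_propagation(g, seeds, rng_seed = 7)$assignment)
  expect_error(label_propagation(g, character()), "seed")
})

test_that("consensus reproduces a shared partition and the exact tail p", {
  memb <- stats::setNames(rep(1:4, each = 5), sprintf("N%02d", 1:20))
  part <- structure(list(assignment = memb), class = "module_partition")
  cons <- consensus_modules(part, part)
  expect_equal(lengths(cons$modules), rep(5L, 4))
  expect_length(cons$unassigned, 0)

  # |universe| 20, |G| = |L| = 5, overlap 4: p = 76/15504 exactly
  p <- stats::phyper(3, 5, 15, 5, lower.tail = FALSE)
  expect_equal(p, 76 / 15504, tolerance = 1e-15)
  row <- cons$pairs[cons$pairs$gn_module == 1 & cons$pairs$lpa_module == 2, ]
  expect_equal(row$overlap, 0)
})

test_that("consensus modules are disjoint subsets of one parent on each side", {
  set.seed(55)
  sc <- synthetic_scenario(seed = 60, n_genes = 32, n_modules = 4,
                           module_size = 8, seed_fraction = 0.125)
  g <- make_ppi(sc)
  gn <- girvan_newman(g)
  lpa <- label_propagation(g, seeds = sc$seed_genes, rng_seed = 3)
  cons <- consensus_modules(gn, lpa)
  all_nodes <- unlist(cons$modules)
  expect_equal(anyDuplicated(all_nodes), 0)
  for (m in cons$modules) {
    expect_equal(length(unique(gn$assignment[m])), 1)
    expect_equal(length(unique(lpa$assignment[m])), 1)
  }
  expect_setequal(c(all_nodes, cons$unassigned), names(gn$assignment))
})

test_that("independent random partitions yield essentially no consensus modules", {
  set.seed(56)
  n_mods <- vapply(1:20, function(i) {
    nodes <- sprintf("n%03d", 1:100)
    a <- structure(list(assignment = stats::setNames(sample(1:5, 100, TRUE), nodes)),
                   class = "module_partition")
    b <- structure(list(assignment = stats::setNames(sample(1:5, 100, TRUE), nodes)),
                   class = "module_partition")
    length(consensus_modules(a, b)$modules)
  }, 0L)
  expect_lte(mean(n_mods), 0.5)
})

test_that("bottlenecks are nodes whose edges span several robust modules", {
  # two triangles bridged through node c: c and d both touch two modules
  tt <- two_triangles()
  memb <- stats::setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  cons <- structure(list(modules = list(c("a", "b", "c"), c("d", "e", "f")),
                         unassigned = character()),
                    class = "consensus_modules")
  cn <- build_community_network(tt, cons)
  expect_setequal(cn$bottlenecks$node, c("c", "d"))
  expect_equal(igraph::ecount(cn$graph), 1)
  expect_equal(igraph::E(cn$graph)$weight, 1)  # one unit-weight bridge

  # fully separated modules: no bottlenecks, no module-graph edges
  two <- weighted_graph(edge_df("a","b", "c","d"))
  cons2 <- structure(list(modules = list(c("a", "b"), c("c", "d")),
                          unassigned = character()),
                     class = "consensus_modules")
  cn2 <- build_community_network(two, cons2)
  expect_equal(nrow(cn2$bottlenecks), 0)
  expect_equal(igraph::ecount(cn2$graph), 0)
})

test_that("partition comparison recovers identity and independence extremes", {
  memb <- stats::setNames(rep(1:3, each = 10), sprintf("x%02d", 1:30))
  expect_equal(compare_partitions(memb, memb), 1)
  set.seed(57)
  shuffled <- stats::setNames(sample(memb), names(memb))
  expect_lt(abs(compare_partitions(memb, shuffled)), 0.35)
})
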