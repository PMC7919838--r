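test_that("generators are pure functions of the scenario seed", {
  sc <- synthetic_scenario(seed = 7, n_genes = 48, n_modules = 3,
                           module_size = 10)
  key <- function(g) {
    e <- igraph::as_data_frame(g)
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  expect_identical(key(make_ppi(sc)), key(make_ppi(sc)))
  expect_identical(make_expression(sc)$values, make_expression(sc)$values)
  o1 <- make_ontology(sc); o2 <- make_ontology(sc)
  expect_identical(o1$dag$edges, o2$dag$edges)
  expect_identical(unclass(o1$ann), unclass(o2$ann))
})

test_that("generated graphs stay connected even without inter-module edges", {
  sc <- synthetic_scenario(seed = 8, n_genes = 30, n_modules = 3,
                           module_size = 10, p_in = 0.8, p_out = 0)
  expect_message(g <- make_ppi(sc), "bridge")
  expect_true(igraph::is_connected(g))
})

test_that("the degree distribution is heavier-tailed than same-density noise", {
  set.seed(71)
  wins <- vapply(1:20, function(i) {
    sc <- synthetic_scenario(seed = i)
    g <- make_ppi(sc)
    er <- igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g))
    gini_coef(igraph::degree(g)) > gini_coef(igraph::degree(er))
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("a null expression scenario yields only calibration-level discoveries", {
  sc <- synthetic_scenario(seed = 9, effect_log2fc = 0)
  expr <- make_expression(sc)
  deg <- screen_degs(expr, adj_p_max = 0.05, min_abs_log2fc = 0)
  expect_lte(mean(deg$adj_p < 0.05), 0.05 + 3 * 0.02)
})

test_that("planted differential genes are recovered with high sensitivity", {
  sens <- vapply(1:50, function(i) {
    sc <- synthetic_scenario(seed = 300 + i, n_genes = 60, n_modules = 2,
                             module_size = 15)
    deg <- screen_degs(make_expression(sc))
    planted <- unlist(sc$modules)
    mean(deg$direction[match(planted, deg$gene)] != "ns")
  }, 0)
  expect_gte(mean(sens), 0.95)
})

test_that("within-module expression pairs carry more mutual information", {
  set.seed(72)
  wins <- vapply(1:10, function(i) {
    sc <- synthetic_scenario(seed = 400 + i, n_genes = 60, n_modules = 2,
                             module_size = 15)
    expr <- make_expression(sc)
    m1 <- sc$modules[[1]]
    bg <- setdiff(sc$genes, unlist(sc$modules))
    mi_of <- function(pairs) mean(vapply(seq_len(nrow(pairs)), function(k)
      mutual_information(expr$values[pairs[k, 1], ],
                         expr$values[pairs[k, 2], ]), 0))
    within <- t(replicate(25, sample(m1, 2)))
    between <- t(replicate(25, sample(bg, 2)))
    mi_of(within) > mi_of(between)
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("coherent annotations make within-module genes more similar", {
  for (i in 1:5) {
    sc <- synthetic_scenario(seed = 500 + i, n_genes = 40, n_modules = 2,
                             module_size = 10, coherence = 1)
    onto <- make_ontology(sc)
    m1 <- sc$modules[[1]]; m2 <- sc$modules[[2]]
    set.seed(i)
    sim_of <- function(a, b) mean(vapply(1:20, function(k)
      gene_similarity(onto$dag, onto$ann, sample(a, 1), sample(b, 1)), 0),
      na.rm = TRUE)
    expect_gt(sim_of(m1, m1), sim_of(m1, m2))
  }
})

test_that("random annotations show no module coherence", {
  diffs <- vapply(1:5, function(i) {
    sc <- synthetic_scenario(seed = 600 + i, n_genes = 40, n_modules = 2,
                             module_size = 10, coherence = 0)
    onto <- make_ontology(sc)
    m1 <- sc$modules[[1]]; m2 <- sc$modules[[2]]
    set.seed(i)
    sim_of <- function(a, b) mean(vapply(1:30, function(k)
      gene_similarity(onto$dag, onto$ann, sample(a, 1), sample(b, 1)), 0),
      na.rm = TRUE)
    sim_of(m1, m1) - sim_of(m1, m2)
  }, 0)
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("scenario export writes the four input kinds plus a manifest", {
  sc <- synthetic_scenario(seed = 10, n_genes = 40, n_modules = 2,
                           module_size = 10)
  dir <- withr::local_tempdir()
  paths <- write_scenario(sc, dir)
  expect_true(all(vapply(unlist(paths), file.exists, TRUE)))
  g <- read_edge_list(paths$ppi)
  expect_equal(igraph::vcount(g), 40)
  seeds <- read_seed_list(paths$seeds)
  expect_setequal(seeds$ids, sc$seed_genes)
  dag <- read_ontology_tsv(paths$ontology)
  ann <- read_annotations(paths$annotations, dag)
  expect_true(all(sc$genes %in% names(ann)))
  expr <- read_expression(paths$expression)
  expect_equal(dim(expr$values), c(40L, sc$n_tumor + sc$n_normal))
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$seed, 10)
})
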