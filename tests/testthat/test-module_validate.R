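test_that("mutual information hits its closed forms at the extremes", {
  set.seed(61)
  x <- rnorm(1000)
  # identical profiles: entropy of equal-frequency bins = log(bins)
  expect_equal(mutual_information(x, x, bins = 5), log(5), tolerance = 1e-12)
  # independent profiles: near zero (plug-in bias ~ (B-1)^2 / 2n)
  expect_lt(mutual_information(x, sample(x), bins = 5), 0.05)
  expect_error(mutual_information(x, x[-1]), "equal length")
})

test_that("mutual information approximates the Gaussian closed form", {
  set.seed(3)
  n <- 1e4
  z <- rnorm(n)
  y <- 0.9 * z + sqrt(1 - 0.81) * rnorm(n)
  truth <- -0.5 * log(1 - 0.81)
  est <- mutual_information(z, y, bins = 10)
  expect_lt(abs(est - truth) / truth, 0.20)
})

test_that("the module score matches hand substitution", {
  # two seeds, no non-seed pairs: W = mean f over the module
  w <- module_score_w(f = c(s1 = 2, s2 = 4), d = c(s1 = 3, s2 = 3),
                      is_seed = c(s1 = TRUE, s2 = TRUE),
                      edges = matrix(character(), 0, 2), mi = function(u, v) 0)
  expect_equal(w, 3)

  # matched f/d ratios cancel the penalty term: W = 3/m = 1
  w2 <- module_score_w(f = c(s = 3, u = 2, v = 4),
                       d = c(s = 1, u = 2, v = 4),
                       is_seed = c(s = TRUE, u = FALSE, v = FALSE),
                       edges = rbind(c("s", "u"), c("u", "v")),
                       mi = function(u, v) 5)
  expect_equal(w2, 1)

  # four-node worked example, straight substitution:
  # seeds s1 (f=6), non-seeds u (f=4, d=2), v (f=1, d=1), t (f=2, d=4)
  # edges s1-u, u-v, v-t; k = 3; non-seed pairs: (u,v), (v,t)
  # W = 6/4 - (1/3) * [ (4/2 - 1/1)^2 * MI(u,v) + (1/1 - 2/4)^2 * MI(v,t) ]
  mi_tab <- c("u|v" = 0.3, "t|v" = 0.6)
  expected <- 6 / 4 - (1 / 3) * ((2 - 1)^2 * 0.3 + (1 - 0.5)^2 * 0.6)
  w3 <- module_score_w(f = c(s1 = 6, u = 4, v = 1, t = 2),
                       d = c(s1 = 9, u = 2, v = 1, t = 4),
                       is_seed = c(s1 = TRUE, u = FALSE, v = FALSE, t = FALSE),
                       edges = rbind(c("s1", "u"), c("u", "v"), c("v", "t")),
                       mi = mi_tab)
  expect_equal(w3, expected, tolerance = 1e-12)

  expect_error(module_score_w(f = c(a = NA), d = c(a = 1),
                              is_seed = c(a = FALSE),
                              edges = matrix(character(), 0, 2),
                              mi = NULL), "missing f")
})

test_that("the module score is invariant to relabeling and linear in seed f", {
  set.seed(62)
  f <- c(a = 3, b = 1, c = 2, d = 0.5)
  d <- c(a = 2, b = 3, c = 1, d = 2)
  is_seed <- c(a = TRUE, b = FALSE, c = FALSE, d = FALSE)
  edges <- rbind(c("b", "c"), c("c", "d"), c("a", "b"))
  mi <- function(u, v) 0.4
  w <- module_score_w(f, d, is_seed, edges, mi)
  ren <- c(a = "w1", b = "w2", c = "w3", d = "w4")
  w_ren <- module_score_w(stats::setNames(f, ren), stats::setNames(d, ren),
                          stats::setNames(is_seed, ren),
                          rbind(c("w2", "w3"), c("w3", "w4"), c("w1", "w2")),
                          mi)
  expect_equal(w, w_ren)
  # doubling seed f doubles the first term only
  f2 <- f; f2["a"] <- 6
  expect_equal(module_score_w(f2, d, is_seed, edges, mi) - w, 3 / 4)
})

test_that("permutation p-values are reproducible, bounded and extreme-capable", {
  sc <- synthetic_scenario(seed = 63, n_genes = 60, n_modules = 3,
                           module_size = 10)
  g <- make_ppi(sc)
  expr <- make_expression(sc, g)
  pt1 <- permutation_test(g, sc$disease_module, expr, seeds = sc$seed_genes,
                          n_perm = 50, rng_seed = 9)
  pt2 <- permutation_test(g, sc$disease_module, expr, seeds = sc$seed_genes,
                          n_perm = 50, rng_seed = 9)
  expect_identical(pt1$null, pt2$null)
  expect_gte(pt1$p, 1 / 51)
  expect_lte(pt1$p, 1)
  expect_error(permutation_test(g, c(sc$disease_module, "nope"), expr,
                                seeds = sc$seed_genes, n_perm = 10),
               "outside the network")
})

test_that("an unbeatable module attains the minimal smoothed p-value", {
  sc <- synthetic_scenario(seed = 64, n_genes = 60, n_modules = 3,
                           module_size = 10, effect_log2fc = 8,
                           effect_attenuation = 0.01)
  g <- make_ppi(sc)
  expr <- make_expression(sc, g)
  # the module consisting of exactly the (strongly differential) seed
  # genes maximizes W: any other same-size set replaces a high-f seed
  # with a non-seed, so no null draw can reach it
  dm_seeds <- intersect(sc$seed_genes, sc$disease_module)
  pt <- permutation_test(g, dm_seeds, expr, seeds = dm_seeds,
                         n_perm = 200, rng_seed = 10)
  expect_equal(pt$p, 1 / 201)
  expect_true(all(pt$null < pt$observed))
})

test_that("more permutations shrink the Monte-Carlo error of p", {
  sc <- synthetic_scenario(seed = 65, n_genes = 50, n_modules = 2,
                           module_size = 10)
  g <- make_ppi(sc)
  expr <- make_expression(sc, g)
  inputs <- module_score_inputs(g, expr, sc$seed_genes)
  ps <- function(n_perm, reps) vapply(seq_len(reps), function(i)
    permutation_test(g, sc$disease_module, expr, seeds = sc$seed_genes,
                     n_perm = n_perm, rng_seed = 100 + i,
                     inputs = inputs)$p, 0)
  sd_small <- sd(ps(40, 12))
  sd_big <- sd(ps(800, 12))
  expect_lt(sd_big, sd_small)
})
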