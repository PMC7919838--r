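test_that("edge-list reading collapses duplicates, filters and drops loops", {
  f <- withr::local_tempfile()
  writeLines(c("A\tB\t0.9", "B\tC\t0.8", "A\tB\t0.5"), f)
  g <- read_edge_list(f, min_weight = 0)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  e <- igraph::as_data_frame(g)
  expect_equal(e$weight[e$from == "A" | e$to == "A"], 0.9)

  g2 <- read_edge_list(f, min_weight = 0.85)
  expect_setequal(igraph::V(g2)$name, c("A", "B"))
  expect_equal(igraph::ecount(g2), 1)

  writeLines(c("A\tA\t0.9", "A\tB\t0.5"), f)
  expect_message(g3 <- read_edge_list(f), "self-loop")
  expect_equal(igraph::ecount(g3), 1)
})

test_that("malformed and empty edge lists raise informative errors", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "A\tB\t0.9", "oops"), f)
  expect_error(read_edge_list(f), "line 3")
  writeLines("A\tB\t0.2", f)
  expect_error(read_edge_list(f, min_weight = 0.5), "empty graph")
})

string_fixture <- function(rows) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  hdr <- paste(c("protein1", "protein2", "neighborhood", "fusion",
                 "cooccurence", "coexpression", "experimental", "database",
                 "textmining", "combined_score"), collapse = " ")
  writeLines(c(hdr, rows), f)
  f
}

test_that("STRING reader keeps a single strong channel and drops excluded ones", {
  f <- string_fixture("p1 p2 0 0 0 0 950 0 0 950")
  g <- read_string_tsv(f, 0.7, exclude_channels = "textmining")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 0.95, tolerance = 1e-3)

  f2 <- string_fixture("p1 p2 0 0 0 0 0 0 990 990")
  expect_error(read_string_tsv(f2, 0.7, exclude_channels = "textmining"),
               "empty graph")
  expect_error(read_string_tsv(f2, 0.7, exclude_channels = "telepathy"),
               "unknown channel")
})

test_that("STRING combination matches a hand evaluation of the formula", {
  # two channels at 0.6 with prior 0.041:
  # corrected s = (0.6 - 0.041) / (1 - 0.041); combined (no prior)
  # 1 - (1 - s)^2; then prior added back once
  s <- (0.6 - 0.041) / (1 - 0.041)
  tot_nop <- 1 - (1 - s)^2
  expected <- tot_nop + 0.041 * (1 - tot_nop)
  f <- string_fixture("p1 p2 0 0 0 600 600 0 0 700")
  g <- read_string_tsv(f, 0.7, exclude_channels = character())
  expect_equal(igraph::E(g)$weight, expected, tolerance = 1e-12)
  expect_gt(expected, 0.7)  # kept at the default threshold
})

test_that("STRING threshold filtering is monotone", {
  set.seed(4)
  rows <- vapply(1:40, function(i) {
    sc <- sample(0:1000, 7, replace = TRUE) * rbinom(7, 1, 0.4)
    paste(c(paste0("a", i), paste0("b", i), sc, max(sc)), collapse = " ")
  }, "")
  f <- string_fixture(rows)
  lo <- read_string_tsv(f, 0.3)
  hi <- read_string_tsv(f, 0.8)
  ends_of <- function(g) {
    e <- igraph::as_data_frame(g)
    paste(pmin(e$from, e$to), pmax(e$from, e$to))
  }
  expect_true(all(ends_of(hi) %in% ends_of(lo)))
})

test_that("seed mapping restricts to the largest component and reports losses", {
  g <- weighted_graph(edge_df("A","B", "C","D", "D","E"))
  s <- seed_set(c("C", "Z"), "test")
  expect_message(m <- map_seeds(g, s), "not in the largest component|seed")
  expect_setequal(igraph::V(m)$name, c("C", "D", "E"))
  expect_equal(graph_seeds(m), "C")
  expect_true("Z" %in% igraph::graph_attr(m, "unmapped_seeds"))

  s2 <- seed_set("A")
  expect_error(map_seeds(g, s2), "no seeds in network")
})

test_that("GML and TSV round-trips preserve structure, weights and attributes", {
  g <- weighted_graph(data.frame(node1 = c("Αλφα", "B"), node2 = c("B", "C"),
                                 weight = c(0.123456, 2)))
  igraph::V(g)$is_seed <- c(TRUE, FALSE, FALSE)
  f <- withr::local_tempfile()
  write_network(g, f, "gml")
  g2 <- read_network(f, "gml")
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_equal(sort(igraph::E(g2)$weight), sort(igraph::E(g)$weight))
  expect_equal(igraph::V(g2)$is_seed[match(igraph::V(g)$name, igraph::V(g2)$name)],
               igraph::V(g)$is_seed)

  write_network(g, f, "tsv")
  expect_length(strsplit(readLines(f)[1], "\t")[[1]], 3)
  g3 <- read_network(f, "tsv")
  expect_setequal(igraph::V(g3)$name, igraph::V(g)$name)
})

test_that("round-trip identity holds on randomized graphs", {
  set.seed(11)
  for (i in 1:5) {
    g <- random_connected_graph(sample(5:60, 1))
    igraph::E(g)$weight <- round(runif(igraph::ecount(g), 0.1, 3), 6)
    key <- function(gg) {
      e <- igraph::as_data_frame(gg)
      o <- order(pmin(e$from, e$to), pmax(e$from, e$to))
      paste(pmin(e$from, e$to), pmax(e$from, e$to),
            sprintf("%.6f", e$weight))[o]
    }
    for (fmt in c("gml", "tsv")) {
      f <- withr::local_tempfile()
      write_network(g, f, fmt)
      expect_identical(key(read_network(f, fmt)), key(g))
    }
  }
})
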