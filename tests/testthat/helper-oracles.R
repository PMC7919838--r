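# Independent oracles and small fixture builders. These deliberately avoid
# the code paths they check: brute-force path enumeration instead of
# Brandes, exhaustive partition scans instead of divisive clustering, a
# direct linear solve instead of power iteration.

# --- fixtures ---------------------------------------------------------------

edge_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(node1 = m[, 1], node2 = m[, 2], stringsAsFactors = FALSE)
}

path_graph <- function(ids) {
  weighted_graph(data.frame(node1 = ids[-length(ids)], node2 = ids[-1]))
}

# two triangles a-b-c and d-e-f joined by the bridge c-d
two_triangles <- function() {
  weighted_graph(edge_df("a","b", "a","c", "b","c",
                         "d","e", "d","f", "e","f", "c","d"))
}

random_connected_graph <- function(n, p = 0.3) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  igraph::E(g)$weight <- 1.0
  g
}

# random rooted DAG: term i may take parents among terms with larger index
# (term n is the root); every non-root gets >= 1 parent
random_dag <- function(n_terms = 12, extra_edge_p = 0.2) {
  child <- parent <- relation <- character()
  for (i in seq_len(n_terms - 1)) {
    cands <- (i + 1):n_terms
    par <- if (length(cands) == 1) cands else sample(cands, 1)
    child <- c(child, paste0("t", i)); parent <- c(parent, paste0("t", par))
    relation <- c(relation, sample(c("is_a", "part_of"), 1))
    extra <- cands[cands != par & runif(length(cands)) < extra_edge_p]
    for (e in extra) {
      child <- c(child, paste0("t", i)); parent <- c(parent, paste0("t", e))
      relation <- c(relation, sample(c("is_a", "part_of"), 1))
    }
  }
  ontology_dag(data.frame(child = child, parent = parent,
                          relation = relation, stringsAsFactors = FALSE))
}

# --- RWR oracle -------------------------------------------------------------

rwr_linear_solve <- function(graph, seed_ids, r) {
  A <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  W <- sweep(A, 2, colSums(A), "/")
  nodes <- igraph::V(graph)$name
  p0 <- as.numeric(nodes %in% seed_ids) / length(seed_ids)
  p <- r * solve(diag(length(nodes)) - (1 - r) * W, p0)
  stats::setNames(as.numeric(p), nodes)
}

# --- edge betweenness oracle ------------------------------------------------

# enumerate every simple path between two nodes with DFS, keep the shortest,
# credit each shortest path's edges with 1/(number of shortest paths)
brute_edge_betweenness <- function(graph) {
  nodes <- igraph::V(graph)$name
  adj <- lapply(igraph::adjacent_vertices(graph, nodes), function(v) v$name)
  names(adj) <- nodes
  eb <- new.env(parent = emptyenv())
  ends <- igraph::ends(graph, igraph::E(graph))
  for (i in seq_len(nrow(ends)))
    assign(paste(sort(ends[i, ]), collapse = "|"), 0, envir = eb)
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(cur, visited) {
      if (cur == to) { paths[[length(paths) + 1]] <<- visited; return() }
      for (nb in adj[[cur]])
        if (!nb %in% visited) walk(nb, c(visited, nb))
    }
    walk(from, from)
    paths
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      ps <- all_paths(nodes[i], nodes[j])
      lens <- lengths(ps)
      shortest <- ps[lens == min(lens)]
      credit <- 1 / length(shortest)
      for (p in shortest) {
        for (k in seq_len(length(p) - 1)) {
          key <- paste(sort(p[k:(k + 1)]), collapse = "|")
          assign(key, get(key, envir = eb) + credit, envir = eb)
        }
      }
    }
  }
  keys <- ls(eb)
  stats::setNames(vapply(keys, get, 0, envir = eb), keys)
}

# --- partition enumeration --------------------------------------------------

# all set partitions of seq_len(n) as membership vectors
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    k <- max(p)
    for (lab in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, lab)
  }
  out
}

best_partition_q <- function(graph) {
  nodes <- igraph::V(graph)$name
  qs <- vapply(all_partitions(length(nodes)), function(p)
    modularity_q(graph, stats::setNames(p, nodes)), 0)
  max(qs)
}

# --- misc -------------------------------------------------------------------

gini_coef <- function(x) {
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

scenario_files <- function(scenario, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_scenario(scenario, dir)
}
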