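# Seed-guided node prioritization: random walk with restart (network
# propagation), comparison centralities, and core-node selection.

#' Random walk with restart from a seed set
#'
#' Iterates `p_{t+1} = (1 - r) W p_t + r p_0` until the L1 change falls
#' below `tol`, where `W` is the column-normalized (optionally weighted)
#' adjacency matrix and `p_0` puts mass `1/|seeds|` on each seed. The
#' converged visit probabilities are the ranking statistic: nodes close to
#' the seeds in the network accumulate probability mass.
#'
#' @param graph a connected weighted `igraph` object.
#' @param seeds a `seed_set` or character vector of node names; defaults to
#'   the graph's `is_seed` vertices.
#' @param r restart probability in (0, 1] (default 0.8).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @param weighted use edge weights in the column normalization (default
#'   TRUE); set FALSE for a purely topological walk.
#' @param per_seed run one walk per seed and average the profiles instead of
#'   a single multi-seed walk (default FALSE).
#' @return an `rwr_profile`: list with `score` (named probabilities summing
#'   to 1), `restart`, `iterations`, `residual`.
#' @export
rwr <- function(graph, seeds = NULL, r = 0.8, tol = 1e-10, max_iter = 10000,
                weighted = TRUE, per_seed = FALSE) {
  g <- .check_graph(graph)
  if (r <= 0 || r > 1) stop("restart probability r must be in (0, 1]")
  if (!igraph::is_connected(g)) stop("rwr requires a connected graph")
  nodes <- igraph::V(g)$name
  seed_ids <- if (is.null(seeds)) graph_seeds(g)
              else if (inherits(seeds, "seed_set")) seeds$ids
              else as.character(seeds)
  seed_ids <- intersect(seed_ids, nodes)
  if (length(seed_ids) == 0L) stop("no seeds present in the graph")
  A <- igraph::as_adjacency_matrix(g, attr = if (weighted) "weight" else NULL,
                                   sparse = FALSE)
  cs <- colSums(A)
  if (any(cs == 0)) stop("graph has a zero-strength node; cannot normalize")
  W <- sweep(A, 2L, cs, "/")
  run_one <- function(p0) {
    p <- p0
    for (it in seq_len(max_iter)) {
      p_new <- (1 - r) * (W %*% p) + r * p0
      res <- sum(abs(p_new - p))
      p <- p_new
      if (res < tol) return(list(p = as.numeric(p), it = it, res = res))
    }
    stop(sprintf("rwr did not converge in %d iterations (residual %.3g)",
                 max_iter, res))
  }
  if (per_seed) {
    runs <- lapply(seed_ids, function(s) {
      p0 <- as.numeric(nodes == s)
      run_one(p0)
    })
    p <- rowMeans(vapply(runs, `[[`, numeric(length(nodes)), "p"))
    it <- max(vapply(runs, `[[`, 0L, "it"))
    res <- max(vapply(runs, `[[`, 0.0, "res"))
  } else {
    p0 <- as.numeric(nodes %in% seed_ids) / length(seed_ids)
    out <- run_one(p0)
    p <- out$p; it <- out$it; res <- out$res
  }
  score <- stats::setNames(p, nodes)
  structure(list(score = score, restart = r, iterations = it,
                 residual = res, seeds = seed_ids),
            class = "rwr_profile")
}

#' Standard node centralities
#'
#' Degree, betweenness, closeness and local clustering coefficient on the
#' unweighted topology (closeness normalized within the component:
#' `(n-1) / sum of shortest-path distances`).
#'
#' @param graph a weighted `igraph` object (weights ignored).
#' @return data frame with one row per node.
#' @export
centralities <- function(graph) {
  g <- .check_graph(graph)
  if (igraph::vcount(g) == 0L) stop("graph is empty")
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  data.frame(node = igraph::V(g)$name,
             degree = as.integer(igraph::degree(g)),
             betweenness = igraph::betweenness(g, weights = NA),
             closeness = igraph::closeness(g, weights = NA,
                                           normalized = TRUE),
             clustering = cc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the core network from a propagation profile
#'
#' The core node set is the union of (i) the top `ceiling(top_fraction * n)`
#' non-seed nodes ranked by random-walk score (ties at the cutoff broken by
#' score descending then node ID ascending), (ii) all seeds, and (iii) the
#' first neighbors of seeds. The returned graph is the subgraph induced on
#' that set, optionally restricted to its largest connected component.
#'
#' @param graph the graph the profile was computed on.
#' @param profile an `rwr_profile`.
#' @param seeds a `seed_set`, character vector, or NULL (use graph
#'   attribute).
#' @param top_fraction fraction of non-seed nodes to keep (default 0.10).
#' @param restrict_component restrict to the largest component (default
#'   TRUE).
#' @return induced subgraph; selected-but-disconnected nodes are recorded in
#'   graph attribute `dropped_nodes`.
#' @export
select_core <- function(graph, profile, seeds = NULL, top_fraction = 0.10,
                        restrict_component = TRUE) {
  g <- .check_graph(graph)
  stopifnot(inherits(profile, "rwr_profile"))
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  nodes <- igraph::V(g)$name
  if (!all(names(profile$score) %in% nodes) ||
      !all(nodes %in% names(profile$score)))
    stop("profile was not computed on this graph")
  seed_ids <- if (is.null(seeds)) graph_seeds(g)
              else if (inherits(seeds, "seed_set")) intersect(seeds$ids, nodes)
              else intersect(as.character(seeds), nodes)
  if (length(seed_ids) == 0L) stop("no seeds present in the graph")
  nonseed <- setdiff(nodes, seed_ids)
  sc <- profile$score[nonseed]
  k <- ceiling(top_fraction * length(nonseed))
  top <- nonseed[order(-sc, nonseed)][seq_len(min(k, length(nonseed)))]
  nbrs <- unique(unlist(lapply(
    igraph::adjacent_vertices(g, seed_ids), function(v) v$name)))
  keep <- union(union(top, seed_ids), nbrs)
  sub <- igraph::induced_subgraph(g, keep)
  dropped <- character()
  if (restrict_component) {
    comp <- igraph::components(sub)
    biggest <- which.max(comp$csize)
    dropped <- igraph::V(sub)$name[comp$membership != biggest]
    sub <- igraph::induced_subgraph(sub, which(comp$membership == biggest))
  }
  sub <- igraph::set_graph_attr(sub, "dropped_nodes", dropped)
  igraph::V(sub)$rwr_score <- profile$score[igraph::V(sub)$name]
  igraph::V(sub)$is_seed <- igraph::V(sub)$name %in% seed_ids
  .check_graph(sub)
}

#' Node score table (propagation score + centralities)
#'
#' @param graph the graph.
#' @param profile an `rwr_profile` on the graph.
#' @return data frame with node, rwr_score, is_seed and the four
#'   centralities, sorted by score descending.
#' @export
node_score_table <- function(graph, profile) {
  ct <- centralities(graph)
  ct$rwr_score <- profile$score[ct$node]
  ct$is_seed <- ct$node %in% profile$seeds
  ct <- ct[order(-ct$rwr_score, ct$node), c("node", "rwr_score", "is_seed",
                                            "degree", "betweenness",
                                            "closeness", "clustering")]
  rownames(ct) <- NULL
  ct
}
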