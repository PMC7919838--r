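# Consensus community detection on the weighted core network: divisive
# weighted Girvan-Newman (top-down) and seed-anchored label propagation
# (bottom-up), merged by a hypergeometric intersection test into robust
# modules, then assembled into a module-level "community network" with
# bottleneck genes.

.as_membership <- function(partition) {
  if (inherits(partition, "module_partition")) partition$assignment
  else partition
}

#' Weighted modularity of a partition
#'
#' `Q = sum_i (e_ii - a_i^2)` with `e_ii` the fraction of total edge weight
#' inside module i and `a_i` the fraction of weighted degree attached to
#' module i.
#'
#' @param graph a weighted `igraph`.
#' @param partition a `module_partition` or named membership vector
#'   covering every node.
#' @return modularity Q.
#' @export
modularity_q <- function(graph, partition) {
  g <- .check_graph(graph)
  memb <- .as_membership(partition)
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(memb))) stop("all nodes must be assigned")
  memb <- memb[nodes]
  w <- igraph::E(g)$weight
  tot <- sum(w)
  if (tot == 0) stop("graph has zero total edge weight")
  ends <- igraph::ends(g, igraph::E(g))
  mu <- memb[ends[, 1]]; mv <- memb[ends[, 2]]
  labs <- unique(memb)
  e_ii <- vapply(labs, function(l) sum(w[mu == l & mv == l]) / tot, 0.0)
  strength <- igraph::strength(g, weights = w)
  a_i <- vapply(labs, function(l) sum(strength[memb == l]) / (2 * tot), 0.0)
  sum(e_ii - a_i^2)
}

.relabel <- function(memb) {
  # contiguous integer labels, 1 = largest module
  sizes <- sort(table(memb), decreasing = TRUE)
  map <- stats::setNames(seq_along(sizes), names(sizes))
  stats::setNames(as.integer(map[as.character(memb)]), names(memb))
}

.components_membership <- function(g) {
  comp <- igraph::components(g)
  stats::setNames(comp$membership, igraph::V(g)$name)
}

#' Weighted Girvan-Newman community detection
#'
#' Divisive clustering: repeatedly remove the edge of highest weighted
#' edge betweenness (with `1/weight` as distances, so heavy, high-TFC edges
#' are "short" and survive), recording the partition into connected
#' components each time a component splits; return the recorded partition
#' of maximum weighted modularity. Betweenness ties are broken by
#' lexicographic edge key, making the procedure fully deterministic.
#'
#' @param wcn a connected weighted `igraph`.
#' @param weight_mode `"distance"` (weights are confidences, distances are
#'   `1/weight`; default) or `"count"` (weights used as distances directly).
#' @return a `module_partition`: list with `assignment` (named integer
#'   vector), `method = "gn"`, `Q`, and `trace` (Q at each recorded split).
#' @export
girvan_newman <- function(wcn, weight_mode = c("distance", "count")) {
  weight_mode <- match.arg(weight_mode)
  g0 <- .check_graph(wcn)
  if (!igraph::is_connected(g0)) stop("girvan_newman requires a connected graph")
  g <- g0
  best_memb <- .components_membership(g0)
  best_q <- modularity_q(g0, best_memb)
  trace <- data.frame(n_modules = length(unique(best_memb)), Q = best_q)
  n_comp <- 1L
  while (igraph::ecount(g) > 0L) {
    w <- igraph::E(g)$weight
    dist <- switch(weight_mode,
                   distance = 1 / pmax(w, .Machine$double.eps),
                   count = pmax(w, .Machine$double.eps))
    eb <- igraph::edge_betweenness(g, weights = dist, directed = FALSE)
    mx <- max(eb)
    cand <- which(eb >= mx * (1 - 1e-12))
    if (length(cand) > 1L) {
      ends <- igraph::ends(g, igraph::E(g)[cand])
      keys <- .edge_key(ends[, 1], ends[, 2])
      cand <- cand[order(keys)][1L]
    }
    g <- igraph::delete_edges(g, cand[1L])
    comp <- igraph::components(g)
    if (comp$no > n_comp) {
      n_comp <- comp$no
      memb <- stats::setNames(comp$membership, igraph::V(g)$name)
      q <- modularity_q(g0, memb)
      trace <- rbind(trace, data.frame(n_modules = comp$no, Q = q))
      if (q > best_q) { best_q <- q; best_memb <- memb }
    }
  }
  structure(list(assignment = .relabel(best_memb), method = "gn",
                 Q = best_q, trace = trace),
            class = "module_partition")
}

#' Seed-anchored label propagation
#'
#' Each seed starts with a unique label; all other nodes start unlabeled.
#' Nodes are visited asynchronously in a random order each sweep — all
#' non-seeds before the seeds, so seed labels spread into their
#' neighborhoods before the seeds themselves are re-evaluated — and every
#' node adopts the label with the maximum summed weight of incident edges
#' to labeled neighbors (keeping its current label when it is among the
#' maxima; other ties broken uniformly at random). Sweeps repeat to a fixed
#' point or `max_sweeps`; any node still unlabeled becomes a singleton
#' module. Fully reproducible for a given `rng_seed`.
#'
#' @param wcn a connected weighted `igraph`.
#' @param seeds a `seed_set`, character vector, or NULL (graph attribute).
#' @param rng_seed integer seed controlling visit order and tie-breaks.
#' @param max_sweeps sweep cap (default 100).
#' @return a `module_partition` with `method = "lpa"`.
#' @export
label_propagation <- function(wcn, seeds = NULL, rng_seed = 1L,
                              max_sweeps = 100L) {
  g <- .check_graph(wcn)
  nodes <- igraph::V(g)$name
  seed_ids <- if (is.null(seeds)) graph_seeds(g)
              else if (inherits(seeds, "seed_set")) intersect(seeds$ids, nodes)
              else intersect(as.character(seeds), nodes)
  if (length(seed_ids) == 0L) stop("label propagation needs >=1 seed in the graph")
  n <- length(nodes)
  lab <- rep(NA_integer_, n)
  names(lab) <- nodes
  lab[seed_ids] <- seq_along(seed_ids)
  is_seed_node <- nodes %in% seed_ids
  adj <- igraph::adjacent_vertices(g, nodes)
  adj_idx <- lapply(adj, as.integer)
  inc <- igraph::incident_edges(g, nodes)
  inc_w <- lapply(inc, function(e) igraph::E(g)$weight[as.integer(e)])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    ord <- c(sample(which(!is_seed_node)), sample(which(is_seed_node)))
    for (i in ord) {
      nb <- adj_idx[[i]]
      wts <- inc_w[[i]]
      labs <- lab[nb]
      ok <- !is.na(labs)
      if (!any(ok)) next
      tot <- tapply(wts[ok], labs[ok], sum)
      mx <- max(tot)
      top <- as.integer(names(tot)[tot >= mx * (1 - 1e-12)])
      if (!is.na(lab[i]) && lab[i] %in% top) next
      new_lab <- if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
      if (is.na(lab[i]) || new_lab != lab[i]) {
        lab[i] <- new_lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (anyNA(lab)) {
    free <- max(lab, na.rm = TRUE)
    idx <- which(is.na(lab))
    lab[idx] <- free + seq_along(idx)
  }
  memb <- .relabel(lab)
  structure(list(assignment = memb, method = "lpa",
                 Q = modularity_q(g, memb), rng_seed = rng_seed),
            class = "module_partition")
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Hypergeometric consensus of two partitions
#'
#' For every pair (G, L) of modules from the two partitions, computes the
#' upper-tail hypergeometric probability of an overlap at least as large as
#' observed (population = universe, successes = |G|, draws = |L|). Pairs
#' with `p < p_threshold` and overlap `>= min_overlap` emit the
#' intersection as a robust-module candidate; candidates are resolved by
#' assigning each node to its smallest-p module. Remaining nodes are
#' reported as unassigned.
#'
#' @param gn,lpa `module_partition`s over the same node universe.
#' @param universe character vector of node IDs (defaults to the union of
#'   assigned nodes).
#' @param p_threshold hypergeometric significance threshold (default 0.01).
#' @param min_overlap minimum intersection size (default 3).
#' @return a `consensus_modules` object: `modules` (list of node sets,
#'   size-descending), `provenance` (data frame of emitting pairs),
#'   `unassigned`, `pairs` (all tested pairs with p-values).
#' @export
consensus_modules <- function(gn, lpa, universe = NULL, p_threshold = 0.01,
                              min_overlap = 3L) {
  mg <- .as_membership(gn)
  ml <- .as_membership(lpa)
  if (is.null(universe)) universe <- union(names(mg), names(ml))
  if (!setequal(names(mg), universe) || !setequal(names(ml), universe))
    stop("both partitions must cover the node universe")
  N <- length(universe)
  gsets <- split(names(mg), mg)
  lsets <- split(names(ml), ml)
  pairs <- expand.grid(gn_module = names(gsets), lpa_module = names(lsets),
                       stringsAsFactors = FALSE)
  pairs$overlap <- mapply(function(gi, li)
    length(intersect(gsets[[gi]], lsets[[li]])), pairs$gn_module,
    pairs$lpa_module)
  pairs$size_gn <- lengths(gsets)[pairs$gn_module]
  pairs$size_lpa <- lengths(lsets)[pairs$lpa_module]
  pairs$p <- stats::phyper(pairs$overlap - 1L, pairs$size_gn,
                           N - pairs$size_gn, pairs$size_lpa,
                           lower.tail = FALSE)
  cand <- pairs[pairs$p < p_threshold & pairs$overlap >= min_overlap, ,
                drop = FALSE]
  cand <- cand[order(cand$p, -cand$overlap, cand$gn_module,
                     cand$lpa_module), , drop = FALSE]
  assigned <- character()
  modules <- list()
  prov <- cand[0, , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    nodes <- setdiff(intersect(gsets[[cand$gn_module[i]]],
                               lsets[[cand$lpa_module[i]]]), assigned)
    if (length(nodes) == 0L) next
    modules[[length(modules) + 1L]] <- sort(nodes)
    prov <- rbind(prov, cand[i, , drop = FALSE])
    assigned <- c(assigned, nodes)
  }
  o <- order(-lengths(modules))
  structure(list(modules = modules[o],
                 provenance = prov[o, , drop = FALSE],
                 unassigned = sort(setdiff(universe, assigned)),
                 pairs = pairs),
            class = "consensus_modules")
}

#' Module membership vector from a consensus set
#'
#' @param consensus a `consensus_modules` object.
#' @param universe node universe; unassigned nodes become singleton labels
#'   (useful for partition comparison).
#' @return named integer membership vector.
#' @export
consensus_membership <- function(consensus, universe = NULL) {
  mods <- consensus$modules
  memb <- integer()
  for (i in seq_along(mods))
    memb[mods[[i]]] <- i
  extra <- if (is.null(universe)) consensus$unassigned
           else setdiff(universe, names(memb))
  if (length(extra) > 0L)
    memb[extra] <- length(mods) + seq_along(extra)
  memb
}

#' Adjusted Rand index between two partitions
#'
#' Comparison harness for externally computed partitions (e.g. output files
#' of other clustering tools) as well as internal ones.
#'
#' @param a,b `module_partition`s or named membership vectors over the same
#'   nodes.
#' @return the adjusted Rand index.
#' @export
compare_partitions <- function(a, b) {
  ma <- .as_membership(a)
  mb <- .as_membership(b)
  common <- intersect(names(ma), names(mb))
  if (length(common) == 0L) stop("partitions share no nodes")
  mclust::adjustedRandIndex(ma[common], mb[common])
}

#' Assemble the module-level community network
#'
#' Nodes are robust modules; an edge between two modules carries the summed
#' weight (TFC) of core-network edges crossing between them. Bottlenecks
#' are nodes whose incident edges span at least two robust modules, ranked
#' by the number of modules bridged, then by summed inter-module edge
#' weight. Per-module mean edge weight is reported.
#'
#' @param wcn the weighted core network.
#' @param modules a `consensus_modules` object on `wcn`.
#' @return a `community_network`: `graph` (module-level igraph),
#'   `bottlenecks` (data frame), `module_stats` (data frame).
#' @export
build_community_network <- function(wcn, modules) {
  g <- .check_graph(wcn)
  stopifnot(inherits(modules, "consensus_modules"))
  mods <- modules$modules
  if (length(mods) == 0L) {
    empty_bt <- data.frame(node = character(), own_module = integer(),
                           n_modules = integer(),
                           inter_module_weight = numeric(),
                           modules = character())
    return(structure(list(graph = igraph::make_empty_graph(0, directed = FALSE),
                          bottlenecks = empty_bt,
                          module_stats = data.frame(module = character(),
                                                    size = integer(),
                                                    mean_edge_weight = numeric())),
                     class = "community_network"))
  }
  memb <- rep(NA_integer_, igraph::vcount(g))
  names(memb) <- igraph::V(g)$name
  for (i in seq_along(mods)) memb[mods[[i]]] <- i
  ends <- igraph::ends(g, igraph::E(g))
  w <- igraph::E(g)$weight
  mu <- memb[ends[, 1]]; mv <- memb[ends[, 2]]
  cross <- !is.na(mu) & !is.na(mv) & mu != mv
  if (any(cross)) {
    a <- pmin(mu[cross], mv[cross]); b <- pmax(mu[cross], mv[cross])
    agg <- stats::aggregate(list(weight = w[cross]),
                            by = list(m1 = a, m2 = b), FUN = sum)
    cnt <- stats::aggregate(list(n_edges = w[cross]),
                            by = list(m1 = a, m2 = b), FUN = length)
    agg$n_edges <- cnt$n_edges
  } else {
    agg <- data.frame(m1 = integer(), m2 = integer(),
                      weight = numeric(), n_edges = integer())
  }
  medges <- if (nrow(agg) > 0L)
    data.frame(node1 = paste0("M", agg$m1), node2 = paste0("M", agg$m2),
               weight = agg$weight)
  else data.frame(node1 = character(), node2 = character(),
                  weight = numeric())
  mg <- igraph::graph_from_data_frame(
    medges, directed = FALSE,
    vertices = data.frame(name = paste0("M", seq_along(mods)),
                          size = lengths(mods)))
  # bottlenecks: nodes whose incident edges touch >= 2 robust modules
  bt <- lapply(seq_along(memb), function(i) {
    v <- names(memb)[i]
    nb_e <- which((ends[, 1] == v | ends[, 2] == v) & cross)
    other <- ifelse(ends[nb_e, 1] == v, ends[nb_e, 2], ends[nb_e, 1])
    spanned <- unique(stats::na.omit(c(memb[v], memb[other])))
    if (length(spanned) >= 2L)
      data.frame(node = v, own_module = memb[v],
                 n_modules = length(spanned),
                 inter_module_weight = sum(w[nb_e]),
                 modules = paste(sort(spanned), collapse = ","),
                 stringsAsFactors = FALSE)
    else NULL
  })
  bt <- do.call(rbind, bt)
  if (is.null(bt)) bt <- data.frame(node = character(),
                                    own_module = integer(),
                                    n_modules = integer(),
                                    inter_module_weight = numeric(),
                                    modules = character())
  bt <- bt[order(-bt$n_modules, -bt$inter_module_weight, bt$node), ,
           drop = FALSE]
  rownames(bt) <- NULL
  within_mean <- vapply(seq_along(mods), function(i) {
    idx <- !is.na(mu) & !is.na(mv) & mu == i & mv == i
    if (any(idx)) mean(w[idx]) else NA_real_
  }, 0.0)
  stats_df <- data.frame(module = paste0("M", seq_along(mods)),
                         size = lengths(mods),
                         mean_edge_weight = within_mean)
  structure(list(graph = mg, bottlenecks = bt, module_stats = stats_df),
            class = "community_network")
}

#' Partition table (node, gn, lpa, consensus labels)
#'
#' @param gn,lpa `module_partition`s.
#' @param consensus a `consensus_modules` object.
#' @return data frame with one row per node.
#' @export
partition_table <- function(gn, lpa, consensus) {
  nodes <- sort(names(gn$assignment))
  cm <- consensus_membership(consensus)
  in_mod <- cm[nodes]
  in_mod[!(nodes %in% unlist(consensus$modules))] <- NA_integer_
  data.frame(node = nodes,
             gn_module = gn$assignment[nodes],
             lpa_module = lpa$assignment[nodes],
             consensus_module = in_mod,
             row.names = NULL, stringsAsFactors = FALSE)
}
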