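# Edge prioritization: Brandes edge betweenness, min-max normalization and
# the Topological-Functional Connection (TFC) score
#   TFC_n = 100 * (T*_n + F_n) / |T*_n + F_n - 2|
# where T* is the normalized betweenness and F the gene-level semantic
# similarity of the interactors. The map x -> x / |x - 2| is strictly
# increasing on [0, 2), so TFC ranks edges that are both topologically
# central and functionally coherent highest; the singularity at
# T* + F -> 2 is capped with an epsilon.

# canonical unordered edge key "u|v" with u < v
.edge_key <- function(u, v) {
  ifelse(u < v, paste(u, v, sep = "|"), paste(v, u, sep = "|"))
}

#' Edge betweenness
#'
#' Fractional shortest-path counts accumulated on edges (Brandes), by
#' default on unweighted hop-count paths; with `use_weights = TRUE` edge
#' weights are treated as confidences and `1/weight` as distances.
#'
#' @param graph a connected weighted `igraph` object.
#' @param use_weights use `1/weight` as shortest-path distances (default
#'   FALSE: hop counts).
#' @return named numeric vector keyed `"u|v"` (u < v lexicographically).
#' @export
edge_betweenness_scores <- function(graph, use_weights = FALSE) {
  g <- .check_graph(graph)
  if (!igraph::is_connected(g)) stop("edge betweenness requires a connected graph")
  wts <- if (use_weights) 1 / igraph::E(g)$weight else NA
  eb <- igraph::edge_betweenness(g, weights = wts, directed = FALSE)
  ends <- igraph::ends(g, igraph::E(g))
  stats::setNames(eb, .edge_key(ends[, 1], ends[, 2]))
}

#' Topological-Functional Connection edge scores
#'
#' For each edge n: `T_n` = edge betweenness, `T*_n` = min-max-normalized
#' betweenness over the scored edge set, `F_n` = gene-level semantic
#' similarity of the endpoints, and
#' `TFC_n = 100 * (T*_n + F_n) / max(|T*_n + F_n - 2|, epsilon)`.
#' Edges with an unannotated endpoint get `F_n = 0` and are flagged.
#' If all betweenness values are equal, every `T*_n` is 0.
#'
#' @param graph a connected weighted `igraph` (typically the core network).
#' @param ann an `annotation_map` (or NULL: all F = 0).
#' @param dag an `ontology_dag` (or NULL).
#' @param epsilon cap for the singular denominator (default 1e-6).
#' @param combine term-combination rule passed to [gene_similarity()].
#' @param use_weights passed to [edge_betweenness_scores()].
#' @return an `edge_score_table` data frame: node1, node2, T, T_star, F,
#'   F_missing, TFC; attributes `min_T`, `max_T`, `epsilon`.
#' @export
tfc_scores <- function(graph, ann = NULL, dag = NULL, epsilon = 1e-6,
                       combine = "bma", use_weights = FALSE) {
  g <- .check_graph(graph)
  stopifnot(epsilon > 0)
  ends <- igraph::ends(g, igraph::E(g))
  Tn <- edge_betweenness_scores(g, use_weights = use_weights)
  rngT <- range(Tn)
  Tstar <- if (diff(rngT) == 0) rep(0, length(Tn))
           else (Tn - rngT[1]) / diff(rngT)
  if (is.null(ann) || is.null(dag)) {
    Fn <- rep(NA_real_, length(Tn))
  } else {
    simcache <- new.env(parent = emptyenv())
    Fn <- vapply(seq_len(nrow(ends)), function(i) {
      u <- ends[i, 1]; v <- ends[i, 2]
      gene_similarity(dag, ann, u, v, combine = combine)
    }, 0.0)
  }
  missing_F <- is.na(Fn)
  Fn[missing_F] <- 0
  out <- data.frame(node1 = ends[, 1], node2 = ends[, 2],
                    T = as.numeric(Tn), T_star = as.numeric(Tstar),
                    F = Fn, F_missing = missing_F,
                    TFC = tfc_value(Tstar, Fn, epsilon),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "min_T") <- rngT[1]
  attr(out, "max_T") <- rngT[2]
  attr(out, "epsilon") <- epsilon
  class(out) <- c("edge_score_table", "data.frame")
  out
}

#' TFC value from normalized betweenness and similarity
#'
#' @param t_star normalized betweenness in [0, 1].
#' @param f semantic similarity in [0, 1].
#' @param epsilon denominator cap (default 1e-6).
#' @return `100 * (t_star + f) / max(|t_star + f - 2|, epsilon)`, vectorized.
#' @export
tfc_value <- function(t_star, f, epsilon = 1e-6) {
  x <- t_star + f
  100 * x / pmax(abs(x - 2), epsilon)
}

#' Build the weighted core network
#'
#' Re-weights the core graph's edges with their TFC scores (topology
#' unchanged, node attributes preserved).
#'
#' @param core the core `igraph`.
#' @param scores an `edge_score_table` computed on `core`.
#' @return the weighted core network.
#' @export
build_wcn <- function(core, scores) {
  g <- .check_graph(core)
  stopifnot(inherits(scores, "edge_score_table"))
  ends <- igraph::ends(g, igraph::E(g))
  key_g <- .edge_key(ends[, 1], ends[, 2])
  key_s <- .edge_key(scores$node1, scores$node2)
  idx <- match(key_g, key_s)
  if (anyNA(idx))
    stop("internal consistency error: edge(s) lack a TFC score: ",
         paste(utils::head(key_g[is.na(idx)], 5L), collapse = ", "))
  igraph::E(g)$weight <- scores$TFC[idx]
  .check_graph(g)
}

#' Write / read an edge score table
#'
#' @param scores an `edge_score_table`.
#' @param path file path.
#' @export
write_edge_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_scores
#' @export
read_edge_scores <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("edge_score_table", "data.frame")
  out
}
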