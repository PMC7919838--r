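#' @importFrom stats phyper p.adjust pt quantile rnorm runif rbinom sd var
#' @importFrom utils read.table write.table head combn
NULL

# Graphs are igraph objects: undirected, simple (no loops / multi-edges),
# vertex attribute `name` (opaque case-sensitive IDs), edge attribute
# `weight` >= 0.  All constructors funnel through .check_graph().

.check_graph <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) stop("graph must be undirected")
  if (igraph::any_loop(g)) stop("graph must not contain self-loops")
  if (igraph::any_multiple(g)) stop("graph must not contain duplicate edges")
  if (is.null(igraph::V(g)$name)) stop("graph vertices must be named")
  w <- igraph::E(g)$weight
  if (is.null(w)) igraph::E(g)$weight <- 1.0
  else if (any(w < 0)) stop("edge weights must be non-negative")
  g
}

#' Construct a weighted undirected graph from an edge table
#'
#' @param edges data frame with columns `node1`, `node2` and optionally
#'   `weight` (default 1.0). Duplicate edges are collapsed keeping the
#'   maximum weight; self-loops are dropped with a message.
#' @return an undirected `igraph` object with a `weight` edge attribute.
#' @export
weighted_graph <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  names(edges)[1:2] <- c("node1", "node2")
  if (!"weight" %in% names(edges)) edges$weight <- 1.0
  edges$node1 <- as.character(edges$node1)
  edges$node2 <- as.character(edges$node2)
  loops <- edges$node1 == edges$node2
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0L) stop("empty graph: no edges after filtering")
  # canonical unordered key, collapse duplicates keeping max weight
  key <- ifelse(edges$node1 < edges$node2,
                paste(edges$node1, edges$node2, sep = "\r"),
                paste(edges$node2, edges$node1, sep = "\r"))
  o <- order(key, -edges$weight)
  edges <- edges[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("node1", "node2", "weight")],
                                     directed = FALSE)
  .check_graph(g)
}

#' Read a tab-separated edge list
#'
#' Expected format: `node1 TAB node2 [TAB weight]`, no header, `#` comments
#' allowed. A missing weight column defaults to 1.0; duplicate rows are
#' collapsed keeping the maximum weight; self-loops are dropped.
#'
#' @param path file path.
#' @param min_weight keep edges with weight `>= min_weight` (default 0).
#' @return a weighted `igraph` object.
#' @export
read_edge_list <- function(path, min_weight = 0) {
  stopifnot(min_weight >= 0)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad) > 0L)
    stop(sprintf("malformed row at line %d: expected 2 or 3 tab-separated columns, got %d",
                 idx[bad[1]], nf[bad[1]]))
  n1 <- vapply(fields, `[`, "", 1L)
  n2 <- vapply(fields, `[`, "", 2L)
  w <- vapply(fields, function(f) {
    if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L])) else 1.0
  }, 0.0)
  if (anyNA(w)) {
    bad <- which(is.na(w))[1]
    stop(sprintf("malformed row at line %d: weight is not numeric", idx[bad]))
  }
  df <- data.frame(node1 = n1, node2 = n2, weight = w,
                   stringsAsFactors = FALSE)
  df <- df[df$weight >= min_weight, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty graph: no edges pass min_weight")
  weighted_graph(df)
}

# STRING evidence channels, in column order of STRING's protein.links.detailed
.string_channels <- c("neighborhood", "fusion", "cooccurence",
                      "coexpression", "experimental", "database",
                      "textmining")

# STRING's combination rule: remove the prior from each channel, combine the
# prior-corrected scores as 1 - prod(1 - s_i), then add the prior back once.
.string_combine <- function(scores, prior = 0.041) {
  s <- pmax((scores - prior) / (1 - prior), 0)
  tot_nop <- 1 - prod(1 - s)
  tot_nop + prior * (1 - tot_nop)
}

#' Read a STRING-style interaction table
#'
#' Reads a whitespace/tab-delimited table with header columns `protein1`,
#' `protein2`, the seven STRING evidence channels and `combined_score`
#' (scores on the 0--1000 scale). The combined score is recomputed after
#' zeroing excluded channels, using STRING's combination rule on
#' prior-corrected channel scores, so that excluded evidence does not
#' contribute. Edge weights are the recomputed scores rescaled to [0, 1].
#'
#' @param path file path.
#' @param score_threshold keep edges with recombined score `>` this value
#'   (on the 0--1 scale; default 0.7).
#' @param exclude_channels character vector of channel names to zero out
#'   (e.g. `"textmining"`).
#' @param prior STRING's prior probability of a random true interaction.
#' @return a weighted `igraph` object.
#' @export
read_string_tsv <- function(path, score_threshold = 0.7,
                            exclude_channels = character(), prior = 0.041) {
  stopifnot(score_threshold >= 0, score_threshold <= 1)
  unknown <- setdiff(exclude_channels, .string_channels)
  if (length(unknown) > 0L)
    stop("unknown channel name(s) in exclude_channels: ",
         paste(unknown, collapse = ", "))
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("protein1", "protein2", .string_channels)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("STRING table is missing required column(s): ",
         paste(missing, collapse = ", "))
  use <- setdiff(.string_channels, exclude_channels)
  sc <- as.matrix(tab[, use, drop = FALSE]) / 1000
  comb <- apply(sc, 1L, .string_combine, prior = prior)
  keep <- comb > score_threshold
  if (!any(keep)) stop("empty graph: no edges pass score_threshold")
  weighted_graph(data.frame(node1 = tab$protein1[keep],
                            node2 = tab$protein2[keep],
                            weight = comb[keep],
                            stringsAsFactors = FALSE))
}

#' Seed set constructor
#'
#' @param ids character vector of node IDs (must be distinct).
#' @param label free-text label for reports.
#' @return a `seed_set` object.
#' @export
seed_set <- function(ids, label = "seeds") {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("seed ids must be distinct")
  if (length(ids) == 0L) stop("seed set must be non-empty")
  structure(list(ids = ids, label = label), class = "seed_set")
}

#' Read a seed list file (one ID per line, `#` comments)
#'
#' @param path file path.
#' @param label label for the set (defaults to the file name).
#' @return a `seed_set` object.
#' @export
read_seed_list <- function(path, label = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!grepl("^(#|$)", lines)]
  seed_set(unique(lines), label = label)
}

#' Map seed genes onto a network
#'
#' Flags nodes present in both the graph and the seed set with the vertex
#' attribute `is_seed`, then restricts the graph to its largest connected
#' component (random-walk ranking and divisive clustering both require a
#' connected graph). Seeds that are absent from the graph, or that fall
#' outside the largest component, are recorded in the graph attribute
#' `unmapped_seeds`.
#'
#' @param graph a weighted `igraph` object.
#' @param seeds a `seed_set`.
#' @return the largest component with `is_seed` vertex attributes set.
#' @export
map_seeds <- function(graph, seeds) {
  g <- .check_graph(graph)
  stopifnot(inherits(seeds, "seed_set"))
  comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  g <- igraph::induced_subgraph(g, which(comp$membership == biggest))
  found <- intersect(seeds$ids, igraph::V(g)$name)
  if (length(found) == 0L)
    stop("no seeds in network: none of the seed ids map into the largest component")
  igraph::V(g)$is_seed <- igraph::V(g)$name %in% found
  unmapped <- setdiff(seeds$ids, found)
  g <- igraph::set_graph_attr(g, "unmapped_seeds", unmapped)
  if (length(unmapped) > 0L)
    message(length(unmapped), " seed(s) not in the largest component: ",
            paste(unmapped, collapse = ", "))
  .check_graph(g)
}

#' Graph seeds helper
#'
#' @param graph a graph whose vertices carry an `is_seed` attribute.
#' @return character vector of seed node names.
#' @export
graph_seeds <- function(graph) {
  s <- igraph::V(graph)$is_seed
  if (is.null(s)) character() else igraph::V(graph)$name[as.logical(s)]
}

#' Write a network to GML or TSV
#'
#' GML preserves node attributes (e.g. `is_seed`) and weights; the TSV
#' format is the 3-column edge list (`node1 TAB node2 TAB weight`, weights
#' printed to 6 decimals), which loses isolated vertices and node
#' attributes.
#'
#' @param graph a weighted `igraph` object.
#' @param path output path.
#' @param format `"gml"` or `"tsv"`.
#' @export
write_network <- function(graph, path, format = c("gml", "tsv")) {
  format <- match.arg(format)
  g <- .check_graph(graph)
  if (igraph::vcount(g) == 0L) stop("refusing to write an empty graph")
  if (format == "gml") {
    # GML carries only scalar attributes; drop non-scalar graph metadata
    # and encode logicals as 0/1 (restored on read)
    for (a in igraph::graph_attr_names(g)) {
      v <- igraph::graph_attr(g, a)
      if (!is.atomic(v) || length(v) != 1L)
        g <- igraph::delete_graph_attr(g, a)
      else if (is.logical(v))
        g <- igraph::set_graph_attr(g, a, as.numeric(v))
    }
    for (a in igraph::vertex_attr_names(g))
      if (is.logical(igraph::vertex_attr(g, a)))
        g <- igraph::set_vertex_attr(g, a,
                                     value = as.numeric(igraph::vertex_attr(g, a)))
    igraph::write_graph(g, path, format = "gml")
  } else {
    df <- igraph::as_data_frame(g, what = "edges")
    out <- data.frame(node1 = df$from, node2 = df$to,
                      weight = sprintf("%.6f", df$weight))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path file path.
#' @param format `"gml"` or `"tsv"`.
#' @return a weighted `igraph` object.
#' @export
read_network <- function(path, format = c("gml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") return(read_edge_list(path))
  g <- igraph::read_graph(path, format = "gml")
  g <- igraph::as_undirected(g, mode = "collapse")
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1.0
  if (!is.null(igraph::V(g)$isseed)) {   # GML flattens attribute names
    igraph::V(g)$is_seed <- as.logical(igraph::V(g)$isseed)
    g <- igraph::delete_vertex_attr(g, "isseed")
  }
  if (!is.null(igraph::V(g)$is_seed))
    igraph::V(g)$is_seed <- as.logical(igraph::V(g)$is_seed)
  .check_graph(g)
}
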