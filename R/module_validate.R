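# Module-level significance: the module score
#   W(M) = (1/m) sum_{i in C1} f_i
#        - (1/k) sum_{(u,v) in C2 edges} (f_u/d_u - f_v/d_v)^2 * MI(u,v)
# where m = |M|, k = number of interactions inside M, C1/C2 the seed and
# non-seed nodes of M, f = -log10 p of a tumor-vs-normal t-test, d = degree
# in the primary network, and MI the binned mutual information of the two
# genes' expression profiles. Significance is an empirical permutation
# p-value against matched-size random node sets.

# equal-frequency bin index (rank-based so tied quantile breaks cannot
# collapse bins)
.quantile_bins <- function(x, bins) {
  n <- length(x)
  ceiling(rank(x, ties.method = "first") * bins / n)
}

.mi_from_bins <- function(bx, by, bins) {
  n <- length(bx)
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins)
  px <- tabulate(bx, nbins = bins) / n
  py <- tabulate(by, nbins = bins) / n
  pj <- joint / n
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  max(hx + hy - hxy, 0)
}

#' Mutual information of two numeric profiles
#'
#' Plug-in estimator on equal-frequency (quantile) bins, natural log.
#'
#' @param x,y numeric vectors of equal length (>= 10).
#' @param bins number of bins per margin (default 5).
#' @return estimated mutual information in nats.
#' @export
mutual_information <- function(x, y, bins = 5L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 10L) stop("need >= 10 observations")
  stopifnot(bins >= 2L)
  .mi_from_bins(.quantile_bins(x, bins), .quantile_bins(y, bins), bins)
}

#' Module score W from precomputed ingredients
#'
#' @param f named vector of expression-difference scores (-log p) covering
#'   the module.
#' @param d named vector of primary-network degrees covering the module.
#' @param is_seed named logical: seed status of each module node.
#' @param edges 2-column character matrix of interactions inside the
#'   module (may have zero rows).
#' @param mi function(u, v) returning the mutual information of two
#'   non-seed genes, or a precomputed named vector keyed `"u|v"` (sorted).
#' @return the module score W.
#' @export
module_score_w <- function(f, d, is_seed, edges, mi) {
  m <- length(f)
  nodes <- names(f)
  if (is.null(nodes) || !setequal(nodes, names(is_seed)))
    stop("f and is_seed must be named over the same module nodes")
  miss_d <- setdiff(nodes[!is_seed], names(d))
  if (length(miss_d) > 0L)
    stop("node(s) missing a degree: ", paste(miss_d, collapse = ", "))
  if (anyNA(f)) stop("node(s) missing f: ",
                     paste(nodes[is.na(f)], collapse = ", "))
  seeds <- nodes[as.logical(is_seed[nodes])]
  term1 <- sum(f[seeds]) / m
  edges <- as.matrix(edges)
  k <- nrow(edges)
  if (k == 0L) return(term1)
  ns <- !is_seed[edges[, 1]] & !is_seed[edges[, 2]]
  if (!any(ns)) return(term1)
  u <- edges[ns, 1]; v <- edges[ns, 2]
  mi_vals <- if (is.function(mi)) mapply(mi, u, v)
             else mi[.edge_key(u, v)]
  if (anyNA(mi_vals)) stop("missing mutual information for module pair(s)")
  ratio_u <- f[u] / d[u]
  ratio_v <- f[v] / d[v]
  term1 - sum((ratio_u - ratio_v)^2 * mi_vals) / k
}

#' Precompute module-score ingredients for a network and expression matrix
#'
#' Runs the per-gene tumor-vs-normal Welch t-test once, converts p-values
#' to `-log` scores, bins every gene's profile for fast mutual-information
#' lookups, and caches the network adjacency.
#'
#' @param network the primary PPI `igraph`.
#' @param expr an `expression_matrix` covering (at least) the network
#'   genes.
#' @param seeds a `seed_set`, character vector, or NULL (graph attribute).
#' @param bins mutual-information bins (default 5).
#' @param log_base base of the `-log p` transform (default 10).
#' @return a `module_score_inputs` object.
#' @export
module_score_inputs <- function(network, expr, seeds = NULL, bins = 5L,
                                log_base = 10) {
  g <- .check_graph(network)
  stopifnot(inherits(expr, "expression_matrix"))
  nodes <- igraph::V(g)$name
  missing <- setdiff(nodes, rownames(expr$values))
  if (length(missing) > 0L)
    stop("expression matrix lacks network gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  seed_ids <- if (is.null(seeds)) graph_seeds(g)
              else if (inherits(seeds, "seed_set")) seeds$ids
              else as.character(seeds)
  vals <- expr$values[nodes, , drop = FALSE]
  tum <- expr$group == "tumor"
  w <- .welch_rows(vals[, tum, drop = FALSE], vals[, !tum, drop = FALSE])
  p <- pmax(w$p, .Machine$double.xmin)
  f <- stats::setNames(-log(p, base = log_base), nodes)
  d <- stats::setNames(as.integer(igraph::degree(g)), nodes)
  binmat <- t(apply(vals, 1L, .quantile_bins, bins = bins))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  structure(list(f = f, d = d, bins = bins, binmat = binmat, adj = adj,
                 nodes = nodes, seed_ids = intersect(seed_ids, nodes),
                 log_base = log_base),
            class = "module_score_inputs")
}

# W for a node subset using precomputed inputs
.score_module <- function(inputs, module) {
  idx <- match(module, inputs$nodes)
  sub <- inputs$adj[idx, idx, drop = FALSE]
  pairs <- which(sub & upper.tri(sub), arr.ind = TRUE)
  edges <- cbind(module[pairs[, 1]], module[pairs[, 2]])
  is_seed <- stats::setNames(module %in% inputs$seed_ids, module)
  mi_fun <- function(u, v)
    .mi_from_bins(inputs$binmat[u, ], inputs$binmat[v, ], inputs$bins)
  module_score_w(inputs$f[module], inputs$d, is_seed, edges, mi_fun)
}

#' Permutation test of a module score
#'
#' Computes W for the observed module, then for `n_perm` node sets of the
#' same size drawn uniformly without replacement from the primary network
#' (seed status and induced interaction count recomputed per draw;
#' optionally degree-matched). The empirical p-value uses add-one
#' smoothing: `p = (#(null >= observed) + 1) / (n_perm + 1)`.
#'
#' @param network the primary PPI `igraph`.
#' @param module character vector of module nodes (subset of the network).
#' @param expr an `expression_matrix`.
#' @param seeds seed genes (see [module_score_inputs()]).
#' @param n_perm number of random draws (default 10000).
#' @param rng_seed integer seed.
#' @param degree_matched draw null sets stratified by degree tertile
#'   instead of uniformly (default FALSE).
#' @param inputs optional precomputed `module_score_inputs` (computed if
#'   NULL).
#' @return a `permutation_result`: `observed`, `null` (numeric vector),
#'   `p`, `n_perm`, `rng_seed`.
#' @export
permutation_test <- function(network, module, expr, seeds = NULL,
                             n_perm = 10000L, rng_seed = 1L,
                             degree_matched = FALSE, inputs = NULL) {
  if (is.null(inputs))
    inputs <- module_score_inputs(network, expr, seeds)
  module <- as.character(module)
  if (!all(module %in% inputs$nodes))
    stop("module contains node(s) outside the network")
  if (length(module) > length(inputs$nodes))
    stop("module larger than the network")
  observed <- .score_module(inputs, module)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  sz <- length(module)
  draw <- if (degree_matched) {
    tert <- cut(inputs$d, breaks = stats::quantile(inputs$d,
                  probs = c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
                labels = FALSE)
    strata <- split(inputs$nodes, tert)
    counts <- table(cut(inputs$d[module], breaks = stats::quantile(inputs$d,
                  probs = c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
                  labels = FALSE))
    function() unlist(lapply(names(counts), function(s)
      sample(strata[[s]], min(counts[[s]], length(strata[[s]])))))
  } else {
    function() sample(inputs$nodes, sz)
  }
  null <- vapply(seq_len(n_perm), function(i) .score_module(inputs, draw()),
                 0.0)
  p <- (sum(null >= observed) + 1) / (n_perm + 1)
  structure(list(observed = observed, null = null, p = p,
                 n_perm = n_perm, rng_seed = rng_seed),
            class = "permutation_result")
}
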