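# Synthetic study generators: a planted-partition interaction graph with a
# preferential-attachment background (heavy-tailed degrees), a two-group
# expression matrix with planted differential modules and within-module
# correlation, and a toy ontology whose annotations are coherent with the
# planted modules. Every generator is a pure function of the scenario and
# its seed, so fixtures are reproducible and never stored on disk.

#' Synthetic scenario definition
#'
#' Defaults describe the study conditions the pipeline is designed for:
#' four planted modules of 20 genes on an 80-gene background, dense within
#' (`p_in = 0.9`) and sparse between (`p_out = 0.05`), one module flagged
#' as the disease module with a quarter of its genes as seeds, two-group
#' expression (20 tumor / 20 normal) with |log2 fold change| = 2 effects on
#' planted genes (SD 0.5, within-module correlation 0.6), and a
#' depth-3/branching-4 ontology with coherence 0.9.
#'
#' @param seed RNG seed for all generators.
#' @param n_genes total genes.
#' @param n_modules number of planted modules.
#' @param module_size genes per planted module.
#' @param p_in,p_out within/between edge probabilities (`p_in > p_out`).
#' @param seed_fraction fraction of each planted module's genes used as
#'   seeds (curated disease genes span several functional modules).
#' @param effect_log2fc group mean shift for disease-module genes
#'   (alternating sign across modules).
#' @param effect_attenuation multiplier on `effect_log2fc` for planted
#'   modules other than the disease module (default 0.75): the disease
#'   module concentrates the strongest differential signal, as the largest
#'   disease community does in real tumor cohorts, while the other modules
#'   remain clear of the fold-change threshold.
#' @param effect_sd residual SD of expression values.
#' @param rho within-module expression correlation.
#' @param n_tumor,n_normal samples per group.
#' @param ontology_depth,ontology_branching toy ontology shape.
#' @param coherence probability a planted gene is annotated inside its
#'   module's subtree.
#' @param pa_edges preferential-attachment edges per background gene.
#' @return a `synthetic_scenario` with gene IDs, module membership and
#'   seed genes materialized.
#' @export
synthetic_scenario <- function(seed = 1L, n_genes = 160L, n_modules = 4L,
                               module_size = 20L, p_in = 0.9, p_out = 0.05,
                               seed_fraction = 0.25, effect_log2fc = 2,
                               effect_attenuation = 0.75,
                               effect_sd = 0.5, rho = 0.6,
                               n_tumor = 20L, n_normal = 20L,
                               ontology_depth = 3L, ontology_branching = 4L,
                               coherence = 0.9, pa_edges = 2L) {
  stopifnot(p_in > p_out, p_out >= 0, effect_sd > 0,
            n_modules * module_size <= n_genes,
            seed_fraction > 0, seed_fraction <= 1,
            ontology_depth >= 2L)
  genes <- sprintf("G%03d", seq_len(n_genes))
  modules <- lapply(seq_len(n_modules), function(i)
    genes[((i - 1L) * module_size + 1L):(i * module_size)])
  names(modules) <- paste0("PM", seq_len(n_modules))
  disease_module <- modules[[1L]]
  n_seeds <- max(1L, round(seed_fraction * module_size))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # curated disease genes are known across several functional modules, so
  # each planted module contributes seeds; module 1 is the tracked
  # "disease module" for recovery experiments
  seed_genes <- sort(unlist(lapply(modules, sample, size = n_seeds)))
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_modules = n_modules, module_size = module_size,
                 genes = genes, modules = modules,
                 disease_module = disease_module, seed_genes = seed_genes,
                 p_in = p_in, p_out = p_out,
                 seed_fraction = seed_fraction,
                 effect_log2fc = effect_log2fc,
                 effect_attenuation = effect_attenuation,
                 effect_sd = effect_sd,
                 rho = rho, n_tumor = n_tumor, n_normal = n_normal,
                 ontology_depth = ontology_depth,
                 ontology_branching = ontology_branching,
                 coherence = coherence, pa_edges = pa_edges),
            class = "synthetic_scenario")
}

#' Planted-partition interaction graph with scale-free background
#'
#' Planted-module gene pairs are connected with probability `p_in` inside a
#' module and `p_out` between modules; background genes join one at a time
#' with `pa_edges` edges to existing genes chosen proportionally to degree
#' (preferential attachment), which gives the overall degree distribution a
#' heavy tail. Disconnected fragments are bridged to the giant component
#' (logged via a message).
#'
#' @param scenario a `synthetic_scenario`.
#' @return a weighted `igraph` (unit weights) with `is_seed` vertex
#'   attributes.
#' @export
make_ppi <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(scenario$seed + 101L)
  planted <- unlist(scenario$modules, use.names = FALSE)
  memb <- rep(seq_len(scenario$n_modules), each = scenario$module_size)
  names(memb) <- planted
  pairs <- t(utils::combn(planted, 2L))
  same <- memb[pairs[, 1]] == memb[pairs[, 2]]
  pr <- ifelse(same, scenario$p_in, scenario$p_out)
  keep <- stats::runif(nrow(pairs)) < pr
  n_expected <- sum(pr)
  if (n_expected < length(planted) - 1L)
    stop("infeasible parameters: expected edges fewer than nodes - 1")
  el <- pairs[keep, , drop = FALSE]
  background <- setdiff(scenario$genes, planted)
  deg <- stats::setNames(rep(0L, scenario$n_genes), scenario$genes)
  tb <- table(c(el))
  deg[names(tb)] <- as.integer(tb)
  existing <- planted
  for (gene in background) {
    m <- min(scenario$pa_edges, length(existing))
    prob <- deg[existing] + 1
    targets <- sample(existing, m, prob = prob / sum(prob))
    el <- rbind(el, cbind(rep(gene, m), targets))
    deg[gene] <- deg[gene] + m
    deg[targets] <- deg[targets] + 1L
    existing <- c(existing, gene)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(node1 = el[, 1], node2 = el[, 2], weight = 1.0),
    directed = FALSE, vertices = scenario$genes)
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    biggest <- which.max(comp$csize)
    anchor <- igraph::V(g)$name[comp$membership == biggest][1L]
    others <- setdiff(seq_len(comp$no), biggest)
    bridges <- vapply(others, function(ci)
      igraph::V(g)$name[comp$membership == ci][1L], "")
    message(length(bridges), " bridge edge(s) added to connect fragments")
    g <- igraph::add_edges(g, as.vector(rbind(bridges, anchor)),
                           weight = 1.0)
  }
  igraph::V(g)$is_seed <- igraph::V(g)$name %in% scenario$seed_genes
  .check_graph(g)
}

#' Two-group expression with planted differential modules
#'
#' Background genes are i.i.d. normal in both groups. Planted-module genes
#' share a latent module factor (pairwise correlation `rho`) and receive a
#' tumor-vs-normal mean shift of `effect_log2fc` with alternating sign
#' across modules, so every planted module passes a fold-change screen
#' while the two directions are represented.
#'
#' @param scenario a `synthetic_scenario`.
#' @param graph optional graph whose gene set the matrix must cover
#'   (defaults to the scenario's genes).
#' @return an `expression_matrix` (log2 scale).
#' @export
make_expression <- function(scenario, graph = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  genes <- if (is.null(graph)) scenario$genes else igraph::V(graph)$name
  if (!all(unlist(scenario$modules) %in% genes))
    stop("planted module genes must be present in the graph")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(scenario$seed + 202L)
  n_s <- scenario$n_tumor + scenario$n_normal
  group <- c(rep("tumor", scenario$n_tumor),
             rep("normal", scenario$n_normal))
  vals <- matrix(stats::rnorm(length(genes) * n_s, mean = 8,
                              sd = scenario$effect_sd),
                 nrow = length(genes),
                 dimnames = list(genes,
                                 sprintf("S%03d", seq_len(n_s))))
  rho <- scenario$rho
  for (mi in seq_along(scenario$modules)) {
    mod <- intersect(scenario$modules[[mi]], genes)
    if (length(mod) == 0L) next
    # shared latent factor => pairwise correlation rho within the module
    latent <- stats::rnorm(n_s, sd = scenario$effect_sd)
    vals[mod, ] <- sqrt(1 - rho) * vals[mod, ] +
      sqrt(rho) * matrix(latent, length(mod), n_s, byrow = TRUE) +
      (1 - sqrt(1 - rho)) * 8
    shift <- scenario$effect_log2fc * if (mi %% 2L == 1L) 1 else -1
    if (mi > 1L) shift <- shift * scenario$effect_attenuation
    vals[mod, group == "tumor"] <- vals[mod, group == "tumor"] + shift
  }
  expression_matrix(vals, group)
}

#' Toy ontology with module-coherent annotations
#'
#' Builds a balanced `is_a` tree (branching `ontology_branching`, depth
#' `ontology_depth`) and assigns each planted module one depth-1 subtree.
#' A planted gene is annotated to a random leaf of its module's subtree
#' with probability `coherence`, otherwise (and for background genes) to a
#' random leaf anywhere. Every gene gets two annotations.
#'
#' @param scenario a `synthetic_scenario`.
#' @return list with `dag` (an `ontology_dag`) and `ann` (an
#'   `annotation_map`).
#' @export
make_ontology <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  b <- scenario$ontology_branching
  depth <- scenario$ontology_depth
  if (b < scenario$n_modules)
    stop("ontology_branching must be >= n_modules (one subtree per module)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(scenario$seed + 303L)
  child <- parent <- character()
  level_nodes <- list("T0")            # root
  for (d in seq_len(depth)) {
    prev <- level_nodes[[d]]
    cur <- character()
    for (p in prev) {
      kids <- paste0(p, ".", seq_len(b))
      child <- c(child, kids)
      parent <- c(parent, rep(p, b))
      cur <- c(cur, kids)
    }
    level_nodes[[d + 1L]] <- cur
  }
  dag <- ontology_dag(data.frame(child = child, parent = parent,
                                 relation = "is_a",
                                 stringsAsFactors = FALSE))
  leaves <- level_nodes[[depth + 1L]]
  subtree_root <- level_nodes[[2L]]    # depth-1 terms, one per module
  leaf_of <- function(roots) {
    pool <- leaves[startsWith(leaves, paste0(sample(roots, 1L), "."))]
    sample(pool, 1L)
  }
  ann <- list()
  module_of <- stats::setNames(
    rep(seq_len(scenario$n_modules), each = scenario$module_size),
    unlist(scenario$modules))
  for (gene in scenario$genes) {
    mi <- module_of[gene]
    terms <- vapply(1:2, function(j) {
      if (!is.na(mi) && stats::runif(1) < scenario$coherence)
        leaf_of(subtree_root[mi])
      else sample(leaves, 1L)
    }, "")
    ann[[gene]] <- unique(terms)
  }
  list(dag = dag, ann = annotation_map(ann, dag))
}

#' Write all four synthetic inputs plus a manifest
#'
#' @param scenario a `synthetic_scenario`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named list of written paths.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- make_ppi(scenario)
  expr <- make_expression(scenario, g)
  onto <- make_ontology(scenario)
  paths <- list(
    ppi = file.path(dir, "ppi.tsv"),
    seeds = file.path(dir, "seeds.txt"),
    ontology = file.path(dir, "ontology.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    expression = file.path(dir, "expression.tsv"),
    manifest = file.path(dir, "scenario_manifest.json"))
  write_network(g, paths$ppi, format = "tsv")
  writeLines(c("# synthetic disease seed genes", scenario$seed_genes),
             paths$seeds)
  utils::write.table(onto$dag$edges, paths$ontology, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann_df <- data.frame(
    gene = rep(names(onto$ann), lengths(onto$ann)),
    term = unlist(onto$ann, use.names = FALSE))
  utils::write.table(ann_df, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_expression(expr, paths$expression)
  manifest <- scenario[setdiff(names(scenario),
                               c("genes", "modules", "disease_module"))]
  manifest$modules <- lapply(scenario$modules, identity)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
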