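# Pipeline orchestration: deg -> network -> rwr -> tfc -> wcn ->
# communities -> validate. Each stage writes its table/graph into the
# output directory and appends to a run manifest (parameters, input
# checksums, RNG seeds), so any stage can be re-run from the stored
# intermediates and re-runs are byte-identical.

.pipeline_stages <- c("deg", "network", "rwr", "tfc", "wcn",
                      "communities", "validate")

#' Pipeline run configuration
#'
#' @param graph path to the PPI edge list or STRING TSV.
#' @param seeds path to the seed list.
#' @param ontology path to the ontology TSV/OBO.
#' @param annotations path to the gene-term annotation TSV.
#' @param expression path to the two-group expression TSV.
#' @param out_dir output directory.
#' @param graph_format `"edge_list"` or `"string"`.
#' @param adj_p_max,min_abs_log2fc DEG thresholds.
#' @param score_threshold,exclude_channels STRING reader options.
#' @param restart RWR restart probability in (0, 1].
#' @param top_fraction core-node fraction in (0, 1].
#' @param epsilon TFC denominator cap.
#' @param combine term-combination rule (`bma`, `max`, `avg`).
#' @param contribution relation contribution factors.
#' @param p_threshold,min_overlap consensus parameters.
#' @param n_perm permutation draws.
#' @param rng_seed seed used for LPA order/ties and permutation draws.
#' @param weighted_walk use edge weights in the RWR normalization.
#' @return a validated `run_config`.
#' @export
run_config <- function(graph, seeds, ontology, annotations, expression,
                       out_dir, graph_format = c("edge_list", "string"),
                       adj_p_max = 0.001, min_abs_log2fc = 1.0,
                       score_threshold = 0.7,
                       exclude_channels = "textmining",
                       restart = 0.8, top_fraction = 0.10,
                       epsilon = 1e-6, combine = "bma",
                       contribution = c(is_a = 0.8, part_of = 0.6),
                       p_threshold = 0.01, min_overlap = 3L,
                       n_perm = 10000L, rng_seed = 1L,
                       weighted_walk = TRUE) {
  graph_format <- match.arg(graph_format)
  cfg <- list(graph = graph, seeds = seeds, ontology = ontology,
              annotations = annotations, expression = expression,
              out_dir = out_dir, graph_format = graph_format,
              adj_p_max = adj_p_max, min_abs_log2fc = min_abs_log2fc,
              score_threshold = score_threshold,
              exclude_channels = exclude_channels,
              restart = restart, top_fraction = top_fraction,
              epsilon = epsilon, combine = combine,
              contribution = as.list(contribution),
              p_threshold = p_threshold, min_overlap = min_overlap,
              n_perm = n_perm, rng_seed = rng_seed,
              weighted_walk = weighted_walk)
  .validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

.validate_config <- function(cfg) {
  with(cfg, {
    if (restart <= 0 || restart > 1)
      stop("config error: restart must be in (0, 1]")
    if (top_fraction <= 0 || top_fraction > 1)
      stop("config error: top_fraction must be in (0, 1]")
    if (epsilon <= 0) stop("config error: epsilon must be positive")
    if (adj_p_max <= 0 || adj_p_max > 1)
      stop("config error: adj_p_max must be in (0, 1]")
    if (p_threshold <= 0 || p_threshold > 1)
      stop("config error: p_threshold must be in (0, 1]")
    if (n_perm < 1) stop("config error: n_perm must be >= 1")
    if (!combine %in% c("bma", "max", "avg"))
      stop("config error: combine must be bma, max or avg")
  })
  invisible(TRUE)
}

#' Read a pipeline config from a YAML file
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @param ... overrides applied on top of the file.
#' @return a `run_config`.
#' @export
read_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  if (!is.null(y$contribution)) y$contribution <- unlist(y$contribution)
  do.call(run_config, y)
}

.file_checksum <- function(path) {
  as.character(tools::md5sum(path))
}

#' Run the full pipeline (or a subset of stages)
#'
#' Stages: `deg` (differential screen), `network` (primary PPI of DEG
#' genes + seeds, largest component), `rwr` (node prioritization),
#' `tfc` (core selection + edge scoring), `wcn` (TFC-weighted core
#' network), `communities` (GN + LPA + hypergeometric consensus +
#' community network), `validate` (per-module permutation test). Later
#' stages read intermediates written by earlier ones, so a run can resume
#' from any stage.
#'
#' @param config a `run_config`.
#' @param stages character vector of stages to run (default all, in
#'   order).
#' @return the run manifest (also written to `manifest.json`), invisibly
#'   the full result list as attribute `results`.
#' @export
run_pipeline <- function(config, stages = .pipeline_stages) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest_path <- out("manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(stages = list())
  manifest$config <- unclass(config)
  manifest$inputs <- lapply(config[c("graph", "seeds", "ontology",
                                     "annotations", "expression")],
                            function(p) list(path = p,
                                             md5 = .file_checksum(p)))
  log_stage <- function(name, info = list()) {
    manifest$stages[[name]] <<- c(list(completed = TRUE,
                                       time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                                  info)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  res <- list()

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if ("deg" %in% stages) run_stage("deg", function() {
    expr <- read_expression(config$expression)
    deg <- screen_degs(expr, config$adj_p_max, config$min_abs_log2fc)
    write_deg_table(deg, out("deg_table.tsv"))
    res$deg <<- deg
    log_stage("deg", list(n_genes = nrow(deg),
                          n_significant = sum(deg$direction != "ns")))
  })

  if ("network" %in% stages) run_stage("network", function() {
    g <- switch(config$graph_format,
                edge_list = read_edge_list(config$graph),
                string = read_string_tsv(config$graph,
                                         config$score_threshold,
                                         config$exclude_channels))
    deg <- if (!is.null(res$deg)) res$deg
           else read_deg_table(out("deg_table.tsv"))
    seeds <- read_seed_list(config$seeds)
    keep <- union(deg$gene[deg$direction != "ns"], seeds$ids)
    keep <- intersect(keep, igraph::V(g)$name)
    if (length(keep) == 0L) stop("no DEG genes present in the graph")
    g <- igraph::induced_subgraph(g, keep)
    g <- map_seeds(g, seeds)
    write_network(g, out("primary_network.gml"), format = "gml")
    res$network <<- g
    log_stage("network", list(n_nodes = igraph::vcount(g),
                              n_edges = igraph::ecount(g)))
  })

  get_network <- function() {
    if (!is.null(res$network)) res$network
    else read_network(out("primary_network.gml"), format = "gml")
  }

  if ("rwr" %in% stages) run_stage("rwr", function() {
    g <- get_network()
    prof <- rwr(g, r = config$restart, weighted = config$weighted_walk)
    tab <- node_score_table(g, prof)
    utils::write.table(tab, out("node_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$network <<- g
    res$rwr <<- prof
    log_stage("rwr", list(iterations = prof$iterations,
                          residual = prof$residual))
  })

  get_profile <- function(g) {
    if (!is.null(res$rwr)) return(res$rwr)
    tab <- utils::read.table(out("node_scores.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    structure(list(score = stats::setNames(tab$rwr_score, tab$node),
                   restart = config$restart, iterations = NA,
                   residual = NA, seeds = tab$node[tab$is_seed]),
              class = "rwr_profile")
  }

  if ("tfc" %in% stages) run_stage("tfc", function() {
    g <- get_network()
    prof <- get_profile(g)
    core <- select_core(g, prof, top_fraction = config$top_fraction)
    dag <- read_ontology_tsv(config$ontology,
                             contribution = unlist(config$contribution))
    ann <- read_annotations(config$annotations, dag)
    scores <- tfc_scores(core, ann, dag, epsilon = config$epsilon,
                         combine = config$combine)
    write_network(core, out("core_network.gml"), format = "gml")
    write_edge_scores(scores, out("edge_scores.tsv"))
    res$network <<- g; res$rwr <<- prof
    res$core <<- core; res$scores <<- scores
    log_stage("tfc", list(n_core_nodes = igraph::vcount(core),
                          n_core_edges = igraph::ecount(core)))
  })

  if ("wcn" %in% stages) run_stage("wcn", function() {
    core <- if (!is.null(res$core)) res$core
            else read_network(out("core_network.gml"), format = "gml")
    scores <- if (!is.null(res$scores)) res$scores
              else read_edge_scores(out("edge_scores.tsv"))
    wcn <- build_wcn(core, scores)
    write_network(wcn, out("wcn.gml"), format = "gml")
    res$wcn <<- wcn
    log_stage("wcn", list(n_nodes = igraph::vcount(wcn),
                          n_edges = igraph::ecount(wcn)))
  })

  get_wcn <- function() {
    if (!is.null(res$wcn)) res$wcn
    else read_network(out("wcn.gml"), format = "gml")
  }

  if ("communities" %in% stages) run_stage("communities", function() {
    wcn <- get_wcn()
    gn <- girvan_newman(wcn)
    lpa <- label_propagation(wcn, rng_seed = config$rng_seed)
    cons <- consensus_modules(gn, lpa,
                              p_threshold = config$p_threshold,
                              min_overlap = config$min_overlap)
    cn <- build_community_network(wcn, cons)
    utils::write.table(partition_table(gn, lpa, cons),
                       out("partition.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
      list(pairs = cons$pairs, modules = cons$modules,
           unassigned = cons$unassigned,
           bottlenecks = cn$bottlenecks,
           module_stats = cn$module_stats),
      out("consensus.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    if (igraph::vcount(cn$graph) > 0L)
      write_network(cn$graph, out("module_graph.gml"), format = "gml")
    res$wcn <<- wcn; res$gn <<- gn; res$lpa <<- lpa
    res$consensus <<- cons; res$community_network <<- cn
    log_stage("communities",
              list(gn_modularity = gn$Q, lpa_modularity = lpa$Q,
                   n_robust_modules = length(cons$modules)))
  })

  if ("validate" %in% stages) run_stage("validate", function() {
    g <- get_network()
    cons <- if (!is.null(res$consensus)) res$consensus
            else {
              cj <- jsonlite::read_json(out("consensus.json"),
                                        simplifyVector = TRUE)
              structure(list(modules = lapply(cj$modules, as.character),
                             unassigned = cj$unassigned),
                        class = "consensus_modules")
            }
    expr <- read_expression(config$expression)
    seeds <- read_seed_list(config$seeds)
    inputs <- module_score_inputs(g, expr, seeds)
    reports <- lapply(seq_along(cons$modules), function(i) {
      module <- intersect(cons$modules[[i]], igraph::V(g)$name)
      if (length(module) < 2L)
        return(list(module = paste0("M", i), skipped = TRUE))
      pt <- permutation_test(g, module, expr, seeds,
                             n_perm = config$n_perm,
                             rng_seed = config$rng_seed + i,
                             inputs = inputs)
      list(module = paste0("M", i), size = length(module),
           observed_w = pt$observed, p = pt$p, n_perm = pt$n_perm,
           rng_seed = pt$rng_seed,
           null_mean = mean(pt$null), null_sd = stats::sd(pt$null))
    })
    jsonlite::write_json(reports, out("validation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$validation <<- reports
    log_stage("validate", list(n_modules_tested = length(reports)))
  })

  structure(manifest, results = res)
}
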