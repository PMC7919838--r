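# Wang-method semantic similarity over an ontology DAG. A term's S-values
# propagate from the focal term up through its ancestors, decaying by a
# relation-type contribution factor at each edge; term similarity is the
# shared-ancestor sum of Eq-style S-values, and gene similarity combines the
# pairwise term matrix (best-match average by default, mirroring GOSemSim).

#' Ontology DAG constructor
#'
#' @param edges data frame with columns `child`, `parent`, `relation`
#'   (values `is_a` or `part_of`).
#' @param contribution named numeric vector of semantic contribution
#'   factors per relation type, each in (0, 1).
#' @return an `ontology_dag` object.
#' @export
ontology_dag <- function(edges,
                         contribution = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  names(edges)[1:2] <- c("child", "parent")
  if (!"relation" %in% names(edges)) edges$relation <- "is_a"
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  edges$relation <- as.character(edges$relation)
  unknown <- setdiff(unique(edges$relation), names(contribution))
  if (length(unknown) > 0L)
    stop("relation type(s) without a contribution factor: ",
         paste(unknown, collapse = ", "))
  if (any(contribution <= 0 | contribution >= 1))
    stop("contribution factors must lie in (0, 1)")
  terms <- sort(unique(c(edges$child, edges$parent)))
  # acyclicity check via igraph topological sort
  dg <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                      directed = TRUE,
                                      vertices = terms)
  if (!igraph::is_dag(dg)) stop("ontology edges contain a cycle")
  parents <- split(seq_len(nrow(edges)), edges$child)
  structure(list(terms = terms, edges = edges, parents = parents,
                 contribution = contribution, graph = dg),
            class = "ontology_dag")
}

#' Read an ontology flat file (TSV: child, parent, relation)
#'
#' @param path file path; `#` comments and a header line starting with
#'   `child` are skipped.
#' @param contribution see [ontology_dag()].
#' @return an `ontology_dag`.
#' @export
read_ontology_tsv <- function(path,
                              contribution = c(is_a = 0.8, part_of = 0.6)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (grepl("^child\\b", lines[1])) lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) stop("ontology rows need >=2 columns")
  ontology_dag(data.frame(
    child = vapply(fields, `[`, "", 1L),
    parent = vapply(fields, `[`, "", 2L),
    relation = vapply(fields, function(f)
      if (length(f) >= 3L) f[3L] else "is_a", ""),
    stringsAsFactors = FALSE), contribution)
}

#' Minimal OBO reader
#'
#' Parses only `[Term]` stanzas with `id:`, `is_a:` and
#' `relationship: part_of` lines — enough for standard GO-subset exports.
#'
#' @param path OBO file path.
#' @param contribution see [ontology_dag()].
#' @return an `ontology_dag`.
#' @export
read_obo <- function(path, contribution = c(is_a = 0.8, part_of = 0.6)) {
  lines <- readLines(path, warn = FALSE)
  child <- parent <- relation <- character()
  cur <- NA_character_
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NA; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
    else if (grepl("^is_a:", ln) && !is.na(cur)) {
      child <- c(child, cur)
      parent <- c(parent, trimws(sub("^is_a:", "", ln)))
      relation <- c(relation, "is_a")
    } else if (grepl("^relationship:\\s*part_of", ln) && !is.na(cur)) {
      child <- c(child, cur)
      parent <- c(parent, trimws(sub("^relationship:\\s*part_of", "", ln)))
      relation <- c(relation, "part_of")
    }
  }
  if (length(child) == 0L) stop("no is_a/part_of relationships found")
  ontology_dag(data.frame(child = child, parent = parent,
                          relation = relation, stringsAsFactors = FALSE),
               contribution)
}

#' Gene-to-term annotation map
#'
#' @param map data frame with columns `gene`, `term`, or a named list of
#'   term-ID character vectors.
#' @param dag the `ontology_dag` the terms must belong to.
#' @return an `annotation_map` (named list gene -> term set).
#' @export
annotation_map <- function(map, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (is.data.frame(map)) {
    names(map)[1:2] <- c("gene", "term")
    map <- lapply(split(as.character(map$term), as.character(map$gene)),
                  unique)
  }
  bad <- setdiff(unique(unlist(map)), dag$terms)
  if (length(bad) > 0L)
    stop("annotation uses term(s) absent from the DAG: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  empty <- names(map)[lengths(map) == 0L]
  if (length(empty) > 0L)
    message(length(empty), " gene(s) carry no annotations")
  structure(map, class = "annotation_map")
}

#' Read an annotation TSV (gene, term)
#'
#' @param path file path.
#' @param dag the `ontology_dag`.
#' @return an `annotation_map`.
#' @export
read_annotations <- function(path, dag) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (grepl("^gene\\b", lines[1])) lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  annotation_map(data.frame(gene = vapply(fields, `[`, "", 1L),
                            term = vapply(fields, `[`, "", 2L),
                            stringsAsFactors = FALSE), dag)
}

#' S-values of a focal ontology term
#'
#' Computes the semantic contribution of every ancestor `t` of the focal
#' term `A`: `S_A(A) = 1`, and for each ancestor the maximum over its
#' children within the ancestor closure of `w_e * S_A(child)`, where `w_e`
#' is the contribution factor of the child-parent relation. The semantic
#' value `SV(A)` is the sum of S-values over the closure.
#'
#' @param dag an `ontology_dag`.
#' @param term focal term ID.
#' @return list with `term`, `ancestors` (the closure, including `term`),
#'   `s` (named S-values) and `sv`.
#' @export
s_values <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$terms) stop("unknown term: ", term)
  # ancestor closure by upward traversal
  closure <- character()
  frontier <- term
  while (length(frontier) > 0L) {
    closure <- union(closure, frontier)
    up <- unique(dag$edges$parent[dag$edges$child %in% frontier])
    frontier <- setdiff(up, closure)
  }
  s <- stats::setNames(rep(0, length(closure)), closure)
  s[term] <- 1
  # relax child->parent contributions until stable (closure is a small DAG)
  e <- dag$edges[dag$edges$child %in% closure &
                 dag$edges$parent %in% closure, , drop = FALSE]
  w <- dag$contribution[e$relation]
  repeat {
    cand <- w * s[e$child]
    upd <- tapply(cand, e$parent, max)
    new_s <- s
    new_s[names(upd)] <- pmax(new_s[names(upd)], upd)
    if (all(new_s == s)) break
    s <- new_s
  }
  list(term = term, ancestors = closure, s = s, sv = sum(s))
}

#' Wang semantic similarity between two ontology terms
#'
#' `sim(A, B) = sum over shared ancestors of (S_A(t) + S_B(t)) /
#' (SV(A) + SV(B))`; 0 when the ancestor closures are disjoint.
#'
#' @param dag an `ontology_dag`.
#' @param a,b term IDs.
#' @return similarity in [0, 1].
#' @export
term_similarity <- function(dag, a, b) {
  sa <- s_values(dag, a)
  sb <- s_values(dag, b)
  shared <- intersect(sa$ancestors, sb$ancestors)
  if (length(shared) == 0L) return(0)
  sum(sa$s[shared] + sb$s[shared]) / (sa$sv + sb$sv)
}

# pairwise term-similarity matrix with S-value caching
.term_sim_matrix <- function(dag, terms1, terms2) {
  all_terms <- union(terms1, terms2)
  cache <- lapply(stats::setNames(all_terms, all_terms),
                  function(t) s_values(dag, t))
  m <- matrix(0, length(terms1), length(terms2),
              dimnames = list(terms1, terms2))
  for (i in terms1) {
    for (j in terms2) {
      si <- cache[[i]]; sj <- cache[[j]]
      shared <- intersect(si$ancestors, sj$ancestors)
      if (length(shared) > 0L)
        m[i, j] <- sum(si$s[shared] + sj$s[shared]) / (si$sv + sj$sv)
    }
  }
  m
}

#' Gene-level semantic similarity
#'
#' Combines the pairwise term-similarity matrix of two genes' annotation
#' sets. `bma` (best-match average, the default) averages each term's best
#' match in the other set over both directions; `max` and `avg` are the
#' matrix maximum and mean.
#'
#' @param dag an `ontology_dag`.
#' @param ann an `annotation_map`.
#' @param g1,g2 gene IDs.
#' @param combine `"bma"`, `"max"` or `"avg"`.
#' @return similarity in [0, 1], or `NA_real_` if either gene is
#'   unannotated (the caller decides the fallback).
#' @export
gene_similarity <- function(dag, ann, g1, g2,
                            combine = c("bma", "max", "avg")) {
  combine <- match.arg(combine)
  t1 <- ann[[g1]]; t2 <- ann[[g2]]
  if (is.null(t1) || is.null(t2) || length(t1) == 0L || length(t2) == 0L)
    return(NA_real_)
  m <- .term_sim_matrix(dag, t1, t2)
  switch(combine,
         bma = (sum(apply(m, 1L, max)) + sum(apply(m, 2L, max))) /
               (nrow(m) + ncol(m)),
         max = max(m),
         avg = mean(m))
}
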