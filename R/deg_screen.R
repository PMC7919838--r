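# Two-group differential-expression screen. A vectorized Welch t-test with
# Benjamini-Hochberg adjustment stands in for a moderated-t fit; the DEG
# table format also accepts externally computed results, so the stage is
# swappable.

#' Expression matrix with two-group sample labels
#'
#' @param values numeric matrix, genes x samples, log2 scale, with row and
#'   column names.
#' @param group character/factor of length `ncol(values)` with levels
#'   `tumor` and `normal`.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, group) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene row names and sample column names")
  if (anyDuplicated(rownames(values))) stop("duplicate gene IDs")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  group <- as.character(group)
  stopifnot(length(group) == ncol(values))
  if (!all(group %in% c("tumor", "normal")))
    stop("group labels must be 'tumor' or 'normal'")
  if (length(unique(group)) < 2L) stop("both groups must be non-empty")
  structure(list(values = values, group = group), class = "expression_matrix")
}

#' Read an expression TSV
#'
#' Format: first row sample IDs, second row group labels (`tumor`/`normal`),
#' then one row per gene (`gene_id TAB value ...`).
#'
#' @param path file path.
#' @return an `expression_matrix`.
#' @export
read_expression <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("expression file needs sample row, group row and >=1 gene row")
  samples <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  group <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (samples[1] %in% c("sample", "gene", "")) {
    samples <- samples[-1]
  }
  if (group[1] %in% c("group", "")) group <- group[-1]
  if (length(group) != length(samples))
    stop("group row and sample row have different lengths")
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  genes <- vapply(body, `[`, "", 1L)
  vals <- t(vapply(body, function(f) as.numeric(f[-1L]),
                   numeric(length(samples))))
  rownames(vals) <- genes
  colnames(vals) <- samples
  expression_matrix(vals, group)
}

#' Write an expression matrix in the package's TSV layout
#'
#' @param expr an `expression_matrix`.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(c("gene", colnames(expr$values)), collapse = "\t"),
               paste(c("group", expr$group), collapse = "\t")), con)
  body <- apply(expr$values, 1L, function(v)
    paste(sprintf("%.10g", v), collapse = "\t"))
  writeLines(paste(rownames(expr$values), body, sep = "\t"), con)
  invisible(path)
}

# Vectorized Welch two-sample t-test, returning two-sided p-values.
.welch_rows <- function(x_t, x_n) {
  n1 <- ncol(x_t); n0 <- ncol(x_n)
  m1 <- rowMeans(x_t); m0 <- rowMeans(x_n)
  v1 <- apply(x_t, 1L, stats::var); v0 <- apply(x_n, 1L, stats::var)
  se2 <- v1 / n1 + v0 / n0
  zerovar <- se2 == 0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[zerovar] <- 1
  list(log2fc = m1 - m0, p = p, t = t, zerovar = zerovar)
}

#' Screen differentially expressed genes
#'
#' Per-gene Welch two-sample t-test (tumor vs normal on log2 values) with
#' Benjamini-Hochberg adjustment over all tested genes. A gene is called
#' `up`/`down` when its adjusted p-value is below `adj_p_max` and
#' |log2 fold change| exceeds `min_abs_log2fc` (the default encodes
#' |fold change| > 2); otherwise `ns`. Genes with zero variance in both
#' groups get p = 1 and are flagged, not dropped.
#'
#' @param expr an `expression_matrix`.
#' @param adj_p_max adjusted-p threshold (default 0.001).
#' @param min_abs_log2fc absolute log2 fold-change threshold (default 1).
#' @return a `deg_table` data frame with columns `gene`, `log2fc`, `p`,
#'   `adj_p`, `direction`, `zero_variance`.
#' @export
screen_degs <- function(expr, adj_p_max = 0.001, min_abs_log2fc = 1.0) {
  stopifnot(inherits(expr, "expression_matrix"))
  tum <- expr$group == "tumor"
  if (sum(tum) < 2L || sum(!tum) < 2L) stop("need >=2 samples per group")
  w <- .welch_rows(expr$values[, tum, drop = FALSE],
                   expr$values[, !tum, drop = FALSE])
  adj <- stats::p.adjust(w$p, method = "BH")
  sig <- adj < adj_p_max & abs(w$log2fc) > min_abs_log2fc
  direction <- ifelse(sig & w$log2fc > 0, "up",
                      ifelse(sig & w$log2fc < 0, "down", "ns"))
  out <- data.frame(gene = rownames(expr$values), log2fc = w$log2fc,
                    p = w$p, adj_p = adj, direction = direction,
                    zero_variance = w$zerovar,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Overlap two DEG tables requiring concordant direction
#'
#' Returns genes significant (`up` or `down`) in both tables with the same
#' direction; genes significant in both but with discordant directions are
#' excluded and reported via a message.
#'
#' @param a,b `deg_table` objects.
#' @return a `deg_table` restricted to the concordant overlap (statistics
#'   taken from `a`).
#' @export
overlap_degs <- function(a, b) {
  stopifnot(inherits(a, "deg_table"), inherits(b, "deg_table"))
  sa <- a[a$direction != "ns", , drop = FALSE]
  sb <- b[b$direction != "ns", , drop = FALSE]
  common <- intersect(sa$gene, sb$gene)
  if (length(common) == 0L) {
    warning("no overlapping significant genes")
    out <- sa[0, , drop = FALSE]
    class(out) <- c("deg_table", "data.frame")
    return(out)
  }
  da <- sa$direction[match(common, sa$gene)]
  db <- sb$direction[match(common, sb$gene)]
  discordant <- common[da != db]
  if (length(discordant) > 0L)
    message(length(discordant), " discordant gene(s) excluded: ",
            paste(discordant, collapse = ", "))
  keep <- setdiff(common, discordant)
  out <- sa[match(keep, sa$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Write / read DEG tables
#'
#' @param deg a `deg_table`.
#' @param path file path.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  needed <- c("gene", "log2fc", "p", "adj_p", "direction")
  missing <- setdiff(needed, names(out))
  if (length(missing) > 0L)
    stop("DEG table missing column(s): ", paste(missing, collapse = ", "))
  class(out) <- c("deg_table", "data.frame")
  out
}
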