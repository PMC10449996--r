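## Size-bounded Fisher enrichment of a query gene set against a GMT
## collection, Benjamini-Hochberg FDR, and network-table export.

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with the monotonicity
#' of the cumulative minimum from the largest rank.
#'
#' @param p_values numeric p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(is.na(p_values) | p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Pathway enrichment of a gene set
#'
#' Tests the query set against every pathway of the collection whose size
#' lies strictly between `pathway_min_size` and `pathway_max_size`
#' (pathways with exactly 50 or 1000 members are excluded at defaults),
#' using the same one-sided hypergeometric core as [overlap_test()]. BH
#' FDR is computed across all tested pathways. A pathway passes iff
#' `p < p_threshold`, `fdr < fdr_threshold` and at least
#' `min_pathway_overlap` query genes are among its members.
#'
#' @param query_genes character vector of gene symbols.
#' @param collection a `gene_set_collection` (see [read_gmt()]).
#' @param universe gene universe size (e.g. genes in the annotation).
#' @param config a [pipeline_config()].
#' @return Data frame sorted by p-value, one row per tested pathway:
#'   `pathway_id`, `name`, `pathway_size`, `overlap_count`,
#'   `overlap_genes` (comma-separated), `p_value`, `fdr`, `odds_ratio`,
#'   `passes`.
#' @export
enrich <- function(query_genes, collection, universe,
                   config = pipeline_config()) {
  query_genes <- unique(query_genes)
  sizes <- vapply(collection, function(s) length(s$genes), 1L)
  keep <- sizes > config$pathway_min_size & sizes < config$pathway_max_size
  if (!any(keep)) {
    warning("no pathways within the size bounds (",
            config$pathway_min_size, ", ", config$pathway_max_size, ")",
            call. = FALSE)
    return(data.frame(pathway_id = character(), name = character(),
                      pathway_size = integer(), overlap_count = integer(),
                      overlap_genes = character(), p_value = numeric(),
                      fdr = numeric(), odds_ratio = numeric(),
                      passes = logical()))
  }
  tested <- collection[keep]
  rows <- lapply(names(tested), function(id) {
    s <- tested[[id]]
    res <- overlap_test(query_genes, s$genes, universe,
                        or_method = config$or_method)
    ov <- intersect(query_genes, s$genes)
    data.frame(pathway_id = id, name = s$name,
               pathway_size = length(s$genes),
               overlap_count = length(ov),
               overlap_genes = paste(sort(ov), collapse = ","),
               p_value = res$p_value, odds_ratio = res$odds_ratio)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$passes <- out$p_value < config$p_threshold &
    out$fdr < config$fdr_threshold &
    out$overlap_count >= config$min_pathway_overlap
  out <- out[order(out$p_value, out$pathway_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("pathway_id", "name", "pathway_size", "overlap_count",
          "overlap_genes", "p_value", "fdr", "odds_ratio", "passes")]
}

#' @noRd
set_similarity <- function(x, y, metric) {
  inter <- length(intersect(x, y))
  if (metric == "jaccard") {
    u <- length(union(x, y))
    if (u == 0) 0 else inter / u
  } else {
    m <- min(length(x), length(y))
    if (m == 0) 0 else inter / m
  }
}

#' Pathway network tables
#'
#' Builds Cytoscape-importable node and edge tables from the passing
#' enrichment results: one node per pathway (carrying p-value, odds ratio
#' and overlap count), and an undirected edge between two pathways iff the
#' similarity of their overlap gene sets reaches the threshold. The
#' default metric is the overlap coefficient `|X int Y| / min(|X|, |Y|)`
#' at threshold 0.5.
#'
#' @param results an [enrich()] table (rows with `passes = FALSE` are
#'   dropped).
#' @param edge_metric `"overlap_coefficient"` or `"jaccard"`.
#' @param edge_threshold minimum metric value for an edge.
#' @return List with data frames `nodes` (`pathway_id`, `name`,
#'   `p_value`, `odds_ratio`, `overlap_count`) and `edges`
#'   (`pathway_a`, `pathway_b`, `metric`, `value`).
#' @export
build_network <- function(results,
                          edge_metric = c("overlap_coefficient", "jaccard"),
                          edge_threshold = 0.5) {
  edge_metric <- match.arg(edge_metric)
  res <- results[results$passes, , drop = FALSE]
  nodes <- res[, c("pathway_id", "name", "p_value", "odds_ratio",
                   "overlap_count")]
  rownames(nodes) <- NULL
  gene_sets <- strsplit(res$overlap_genes, ",", fixed = TRUE)
  edges <- data.frame(pathway_a = character(), pathway_b = character(),
                      metric = character(), value = numeric())
  if (nrow(res) >= 2) {
    pairs <- utils::combn(seq_len(nrow(res)), 2)
    vals <- apply(pairs, 2, function(ij)
      set_similarity(gene_sets[[ij[1]]], gene_sets[[ij[2]]], edge_metric))
    keep <- vals >= edge_threshold
    if (any(keep))
      edges <- data.frame(pathway_a = res$pathway_id[pairs[1, keep]],
                          pathway_b = res$pathway_id[pairs[2, keep]],
                          metric = edge_metric, value = vals[keep])
  }
  list(nodes = nodes, edges = edges)
}

#' Write a pathway network as a Cytoscape SIF file
#'
#' Isolated nodes are written as single-column lines so no passing pathway
#' is lost on import.
#'
#' @param network a [build_network()] result.
#' @param path output SIF path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  edge_lines <- if (nrow(network$edges)) {
    paste(network$edges$pathway_a, "overlaps", network$edges$pathway_b,
          sep = "\t")
  } else character()
  connected <- unique(c(network$edges$pathway_a, network$edges$pathway_b))
  isolated <- setdiff(network$nodes$pathway_id, connected)
  writeLines(c(edge_lines, isolated), path)
  invisible(path)
}
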