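#' Pipeline configuration
#'
#' Collects every numeric threshold and convention switch used by the
#' pipeline into a single validated object. Defaults reproduce the study
#' conditions: CNVs between 10 kb and 10 Mb are analysed, genes seen in
#' more than 0.1% of control samples are removed, a critical exon requires
#' expression above the 75th percentile and rare non-synonymous mutation
#' burden below the 75th percentile in at least 50 brain samples, the pLI
#' gate is >= 0.9, and pathway enrichment considers gene sets of more than
#' 50 and fewer than 1000 members with at least 5 overlapping genes at
#' P < 0.05 and Benjamini-Hochberg FDR < 0.01.
#'
#' @param min_cnv_size_bp,max_cnv_size_bp inclusive CNV size window (bp).
#' @param control_freq_threshold genes with control carrier frequency
#'   strictly above this are removed.
#' @param expr_percentile,burden_percentile percentile cut points (0-100)
#'   for the critical-exon rule.
#' @param min_critical_samples minimum number of brain samples in which a
#'   single exon must be critical for its gene to be a critical-exon gene.
#' @param pli_threshold inclusive pLI lower bound for the constraint gate.
#' @param pathway_min_size,pathway_max_size strict (exclusive) pathway size
#'   bounds; a pathway must have more than `pathway_min_size` and fewer
#'   than `pathway_max_size` members to be tested.
#' @param min_pathway_overlap minimum query genes inside a pathway for it
#'   to pass.
#' @param fdr_threshold,p_threshold enrichment significance gates (strict).
#' @param candidate_max_cnv_size_bp size ceiling (bp, inclusive) for
#'   gene-specific CNVs in candidate ranking.
#' @param universe_size positive integer, or `"annotation"` to use the
#'   number of genes with at least one CDS interval in the loaded
#'   annotation.
#' @param seed integer seed propagated to every stochastic component.
#' @param or_method odds-ratio convention: `"sample"` for the cross-product
#'   ratio (a*d)/(b*c) with 0 / Inf conventions, `"cmle"` for the
#'   conditional maximum-likelihood estimate from [stats::fisher.test()].
#' @param expr_threshold_scope `"per_sample"` computes the expression
#'   percentile within each brain sample; `"global"` over the whole matrix.
#' @param percentile_type quantile algorithm passed to [stats::quantile()];
#'   the default 7 is linear interpolation between order statistics.
#' @param control_type_match if `TRUE`, control frequencies are computed
#'   per CNV type; the default pools deletions and duplications
#'   (conservative removal).
#' @param gene_expr_summary how exon values are summarised to a gene-level
#'   value, `"mean"` (default) or `"median"`.
#' @param edge_metric,edge_threshold pathway-network edge rule: metric
#'   (`"overlap_coefficient"` or `"jaccard"`) and minimum value for an
#'   edge to be drawn.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_cnv_size_bp
#' @export
pipeline_config <- function(min_cnv_size_bp = 10000,
                            max_cnv_size_bp = 10000000,
                            control_freq_threshold = 0.001,
                            expr_percentile = 75,
                            burden_percentile = 75,
                            min_critical_samples = 50,
                            pli_threshold = 0.9,
                            pathway_min_size = 50,
                            pathway_max_size = 1000,
                            min_pathway_overlap = 5,
                            fdr_threshold = 0.01,
                            p_threshold = 0.05,
                            candidate_max_cnv_size_bp = 1000000,
                            universe_size = "annotation",
                            seed = 1L,
                            or_method = c("sample", "cmle"),
                            expr_threshold_scope = c("per_sample", "global"),
                            percentile_type = 7L,
                            control_type_match = FALSE,
                            gene_expr_summary = c("mean", "median"),
                            edge_metric = c("overlap_coefficient", "jaccard"),
                            edge_threshold = 0.5) {
  cfg <- list(
    min_cnv_size_bp = as.numeric(min_cnv_size_bp),
    max_cnv_size_bp = as.numeric(max_cnv_size_bp),
    control_freq_threshold = as.numeric(control_freq_threshold),
    expr_percentile = as.numeric(expr_percentile),
    burden_percentile = as.numeric(burden_percentile),
    min_critical_samples = as.integer(min_critical_samples),
    pli_threshold = as.numeric(pli_threshold),
    pathway_min_size = as.numeric(pathway_min_size),
    pathway_max_size = as.numeric(pathway_max_size),
    min_pathway_overlap = as.integer(min_pathway_overlap),
    fdr_threshold = as.numeric(fdr_threshold),
    p_threshold = as.numeric(p_threshold),
    candidate_max_cnv_size_bp = as.numeric(candidate_max_cnv_size_bp),
    universe_size = universe_size,
    seed = as.integer(seed),
    or_method = match.arg(or_method),
    expr_threshold_scope = match.arg(expr_threshold_scope),
    percentile_type = as.integer(percentile_type),
    control_type_match = isTRUE(control_type_match),
    gene_expr_summary = match.arg(gene_expr_summary),
    edge_metric = match.arg(edge_metric),
    edge_threshold = as.numeric(edge_threshold)
  )
  num <- c("min_cnv_size_bp", "max_cnv_size_bp", "control_freq_threshold",
           "expr_percentile", "burden_percentile", "min_critical_samples",
           "pli_threshold", "pathway_min_size", "pathway_max_size",
           "min_pathway_overlap", "fdr_threshold", "p_threshold",
           "candidate_max_cnv_size_bp", "edge_threshold")
  for (f in num) {
    v <- cfg[[f]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field '", f, "' must be a single strictly positive number",
           call. = FALSE)
  }
  if (cfg$min_cnv_size_bp >= cfg$max_cnv_size_bp)
    stop("min_cnv_size_bp must be < max_cnv_size_bp", call. = FALSE)
  if (cfg$pathway_min_size >= cfg$pathway_max_size)
    stop("pathway_min_size must be < pathway_max_size", call. = FALSE)
  if (!identical(cfg$universe_size, "annotation")) {
    u <- suppressWarnings(as.numeric(cfg$universe_size))
    if (is.na(u) || u <= 0 || u != round(u))
      stop("universe_size must be a positive integer or \"annotation\"",
           call. = FALSE)
    cfg$universe_size <- as.integer(u)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file keep their [pipeline_config()] defaults;
#' unknown fields are rejected.
#'
#' @param path path to a YAML file whose keys mirror [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (f in names(x)) cat(sprintf("  %-26s %s\n", f, format(x[[f]])))
  invisible(x)
}
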