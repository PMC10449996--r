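## End-to-end orchestration: filter -> extract -> control-filter -> overlap
## battery -> constraint -> expression profiles -> enrichment -> candidates,
## plus the count/percentage bookkeeping layer.

#' Percentage with retained numerator and denominator
#'
#' Rounds half away from zero at the requested precision (so 31/170 gives
#' 18% and 19/48 gives 40%). The numerator and denominator are retained so
#' every reported percentage can be recomputed exactly.
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @param digits decimal places.
#' @return Object of class `percentage`: list with `value`, `numerator`,
#'   `denominator`, `digits` and a printed `label` like `"18% (31/170)"`.
#' @examples
#' percentage(31, 170)$value  # 18
#' @export
percentage <- function(numerator, denominator, digits = 0) {
  if (length(denominator) != 1 || is.na(denominator) || denominator <= 0)
    stop("denominator must be a positive count", call. = FALSE)
  x <- 100 * numerator / denominator
  v <- sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
  structure(list(value = v, numerator = numerator,
                 denominator = denominator, digits = digits,
                 label = sprintf("%s%% (%d/%d)", format(v), numerator,
                                 denominator)),
            class = "percentage")
}

#' @export
print.percentage <- function(x, ...) {
  cat(x$label, "\n")
  invisible(x)
}

#' Cohort demographic totals
#'
#' Marginal totals by phenotype, sex and site computed by summation only.
#' Accepts either one row per sample, or pre-aggregated rows carrying a
#' count column `n`.
#'
#' @param samples data frame with columns `phenotype`, `sex`, `site` and
#'   optionally `n`.
#' @return List of data frames `by_phenotype`, `by_sex`, `by_site`,
#'   `by_phenotype_site_sex`, and `total`.
#' @export
summarize_cohorts <- function(samples) {
  n <- if ("n" %in% names(samples)) as.numeric(samples$n) else
    rep(1, nrow(samples))
  margin <- function(f) {
    if (nrow(samples) == 0)
      return(data.frame(level = character(), n = numeric()))
    agg <- rowsum(n, samples[[f]])
    data.frame(level = rownames(agg), n = as.numeric(agg),
               row.names = NULL)
  }
  cross <- if (nrow(samples) == 0) {
    data.frame(phenotype = character(), site = character(),
               sex = character(), n = numeric())
  } else {
    key <- paste(samples$phenotype, samples$site, samples$sex, sep = "\r")
    agg <- rowsum(n, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    data.frame(phenotype = vapply(parts, `[[`, "", 1),
               site = vapply(parts, `[[`, "", 2),
               sex = vapply(parts, `[[`, "", 3),
               n = as.numeric(agg), row.names = NULL)
  }
  list(by_phenotype = margin("phenotype"), by_sex = margin("sex"),
       by_site = margin("site"), by_phenotype_site_sex = cross,
       total = sum(n))
}

#' @noRd
stage_count <- function(report, stage, n_in, n_out) {
  report$stages[[stage]] <- list(input = n_in, output = n_out,
                                 excluded = n_in - n_out)
  report
}

#' Run the full pipeline
#'
#' Executes every stage in order on files written by [simulate_study()]
#' or real inputs in the same formats: CNV size filtering, CDS-based gene
#' extraction, control-frequency filtering, the stratified overlap
#' battery, critical-exon/pLI constraint filtering, developmental
#' expression profiling, pathway enrichment with network export, and
#' candidate ranking. Every intermediate table is written to `out_dir`
#' and a run report (counts, de novo CNV bookkeeping with retained
#' numerators/denominators) is serialized as JSON and text.
#'
#' @param paths named list of input paths: `ndd_cnvs`, `ca_cnvs`,
#'   `control_cnvs`, `gene_models`, `pli`, `expression`,
#'   `expression_meta`, `burden`, `gmt`; optional `samples`,
#'   `n_controls`, `gene_models_dialect` (default `"gtf"`).
#' @param config a [pipeline_config()].
#' @param out_dir output directory for stage tables and the report.
#' @return Invisibly, a list with the run `report` and the main stage
#'   outputs (`battery`, `constraint_genes`, `stage_summary`,
#'   `stage_tests`, `enrichment`, `network`, `candidates`, ...).
#' @export
run_pipeline <- function(paths, config = pipeline_config(),
                         out_dir = tempfile("cnvrun")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), percentages = list())

  ## -- inputs ---------------------------------------------------------------
  pli <- read_pli(paths$pli)
  models <- read_gene_models(
    paths$gene_models,
    dialect = if (is.null(paths$gene_models_dialect)) "gtf" else
      paths$gene_models_dialect,
    pli = pli)
  ndd <- read_cnv_table(paths$ndd_cnvs, phenotype_default = "NDD")
  ca <- read_cnv_table(paths$ca_cnvs, phenotype_default = "CA")
  control <- read_cnv_table(paths$control_cnvs,
                            phenotype_default = "control")
  samples <- if (!is.null(paths$samples))
    utils::read.delim(paths$samples, colClasses = "character") else NULL
  n_controls <- if (!is.null(paths$n_controls)) paths$n_controls
    else if (!is.null(samples)) sum(samples$phenotype == "control")
    else length(unique(control$sample_id))
  expr <- read_expression_matrix(paths$expression, paths$expression_meta)
  burden <- read_exon_burden(paths$burden)
  gmt <- read_gmt(paths$gmt)
  e2g <- exon_to_gene_map(models)
  universe <- resolve_universe(config, models)
  if (!is.null(samples)) report$cohorts <- summarize_cohorts(samples)

  ## -- size filter ----------------------------------------------------------
  ndd_f <- filter_cnvs(ndd, config)
  ca_f <- filter_cnvs(ca, config)
  report <- stage_count(report, "size_filter_ndd", nrow(ndd), nrow(ndd_f))
  report <- stage_count(report, "size_filter_ca", nrow(ca), nrow(ca_f))

  ## -- control frequencies --------------------------------------------------
  freq <- control_gene_frequency(control, models,
                                 n_control_samples = n_controls,
                                 config = config)

  ## -- stratified overlap battery -------------------------------------------
  battery <- stratified_overlap_battery(ndd_f, ca_f, models,
                                        freq_map = freq, config = config,
                                        keep_gene_sets = TRUE)
  gene_sets <- attr(battery, "gene_sets")

  ## -- overlapping genes (pooled pathogenic strata, all inheritance) --------
  pooled <- function(type) {
    gs <- gene_sets[[paste("pooled", "pathogenic", type, "all",
                           sep = ".")]]
    intersect(gs$ndd, gs$ca)
  }
  overlap_del <- pooled("deletion")
  overlap_dup <- pooled("duplication")
  overlap_genes <- sort(union(overlap_del, overlap_dup))
  report <- stage_count(report, "overlap_genes",
                        length(union(
                          unlist(gene_sets[["pooled.pathogenic.deletion.all"]]),
                          unlist(gene_sets[["pooled.pathogenic.duplication.all"]]))),
                        length(overlap_genes))

  ## -- constraint filtering -------------------------------------------------
  cem <- critical_exon_matrix(expr, burden, config)
  ce <- ce_genes(cem, e2g, config$min_critical_samples)
  constraint_genes <- constraint_filter(overlap_genes, ce, pli,
                                        config$pli_threshold)
  report <- stage_count(report, "constraint_filter",
                        length(overlap_genes), length(constraint_genes))
  con_summary <- constraint_summary(overlap_genes, cem, e2g, pli, config)

  ## -- expression profiles --------------------------------------------------
  ## pairwise stage tests need >= 3 genes; a near-empty gene list reports
  ## no profile rather than aborting the run
  if (length(constraint_genes) >= 3) {
    summ <- stage_summary(expr, constraint_genes, e2g,
                          summary = config$gene_expr_summary)
    stage_tests <- compare_all_stages(summ)
  } else {
    summ <- NULL
    stage_tests <- data.frame(stage_a = character(),
                              stage_b = character(),
                              p_value = numeric())
  }

  ## -- pathway enrichment ---------------------------------------------------
  enr <- enrich(constraint_genes, gmt, universe, config)
  net <- build_network(enr, config$edge_metric, config$edge_threshold)

  ## -- candidates -----------------------------------------------------------
  case_path <- rbind(ndd_f, ca_f)
  case_path <- case_path[case_path$pathogenicity == "pathogenic", ,
                         drop = FALSE]
  de_novo_genes <- genes_impacted(
    case_path[case_path$inheritance == "de_novo", , drop = FALSE], models)
  candidates <- rank_candidates(
    constraint_genes, case_path, models, config,
    membership = list(de_novo_list = de_novo_genes))

  ## -- de novo CNV bookkeeping ----------------------------------------------
  dn_ndd <- ndd_f[ndd_f$inheritance == "de_novo", , drop = FALSE]
  dn_ca <- ca_f[ca_f$inheritance == "de_novo", , drop = FALSE]
  hits_constraint <- function(calls) {
    if (nrow(calls) == 0) return(0L)
    ht <- gene_hit_table(calls, models)
    length(unique(ht$call_idx[ht$symbol %in% constraint_genes]))
  }
  ov_ndd <- hits_constraint(dn_ndd)
  ov_ca <- hits_constraint(dn_ca)
  report$de_novo <- list(
    n_ndd_cnvs = nrow(dn_ndd), n_ca_cnvs = nrow(dn_ca),
    n_overlapping_ndd = ov_ndd, n_overlapping_ca = ov_ca)
  if (nrow(dn_ndd) > 0)
    report$percentages$ndd_de_novo_overlapping <-
      percentage(ov_ndd, nrow(dn_ndd))
  if (nrow(dn_ca) > 0)
    report$percentages$ca_de_novo_overlapping <-
      percentage(ov_ca, nrow(dn_ca))
  if (ov_ndd + ov_ca > 0) {
    report$percentages$overlapping_from_ndd <-
      percentage(ov_ndd, ov_ndd + ov_ca)
    report$percentages$overlapping_from_ca <-
      percentage(ov_ca, ov_ndd + ov_ca)
  }
  report$counts <- list(
    overlap_genes = length(overlap_genes),
    overlap_deletion_genes = length(overlap_del),
    overlap_duplication_genes = length(overlap_dup),
    constraint_genes = length(constraint_genes),
    ce_genes = length(ce),
    enriched_pathways = sum(enr$passes),
    candidate_genes = sum(candidates$is_candidate),
    non_omim_genes = nrow(attr(candidates, "non_omim")))

  ## -- persist --------------------------------------------------------------
  write_results(c(list(
    overlap_battery = battery,
    constraint_summary = con_summary),
    if (!is.null(summ)) list(
      gene_stage_means = data.frame(
        gene = rownames(summ$gene_stage_means), summ$gene_stage_means),
      stage_stats = summ$stage_stats),
    list(
    stage_tests = stage_tests,
    enrichment = enr,
    network_nodes = net$nodes,
    network_edges = net$edges,
    candidates = candidates)), out_dir)
  write_sif(net, file.path(out_dir, "network.sif"))
  writeLines(constraint_genes, file.path(out_dir, "constraint_genes.txt"))
  write_report(report, out_dir)

  invisible(list(report = report, battery = battery,
                 overlap_genes = overlap_genes,
                 constraint_genes = constraint_genes, ce_genes = ce,
                 constraint_summary = con_summary, stage_summary = summ,
                 stage_tests = stage_tests, enrichment = enr,
                 network = net, candidates = candidates,
                 freq_map = freq, out_dir = out_dir))
}

#' @noRd
write_report <- function(report, out_dir) {
  ser <- report
  ser$percentages <- lapply(report$percentages, unclass)
  jsonlite::write_json(ser, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  txt <- c("Pipeline run report", "===================", "")
  for (nm in names(report$stages)) {
    s <- report$stages[[nm]]
    txt <- c(txt, sprintf("%-24s in: %d  out: %d  excluded: %d", nm,
                          s$input, s$output, s$excluded))
  }
  if (!is.null(report$de_novo)) {
    dn <- report$de_novo
    txt <- c(txt, "",
             sprintf("de novo CNVs: %d NDD, %d CA", dn$n_ndd_cnvs,
                     dn$n_ca_cnvs),
             sprintf("overlapping constraint genes: %d NDD, %d CA CNVs",
                     dn$n_overlapping_ndd, dn$n_overlapping_ca))
  }
  for (nm in names(report$percentages))
    txt <- c(txt, sprintf("%-32s %s", nm, report$percentages[[nm]]$label))
  if (!is.null(report$counts)) {
    txt <- c(txt, "")
    for (nm in names(report$counts))
      txt <- c(txt, sprintf("%-28s %d", nm, report$counts[[nm]]))
  }
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(report)
}
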