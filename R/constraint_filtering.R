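## Critical-exon classification from brain expression plus population
## mutation burden, and the critical-exon-or-pLI constraint gate.

#' Classify critical exons
#'
#' An exon is critical in a brain sample iff its expression is strictly
#' above the 75th percentile of expression over all exons in that sample
#' AND its rare non-synonymous mutation burden is strictly below the 75th
#' percentile of burden over all exons (the burden threshold is computed
#' once; burden is sample-independent). Percentiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7) by
#' default. `config$expr_threshold_scope = "global"` computes a single
#' expression threshold over the whole matrix instead of per sample.
#'
#' @param expr an `exon_expression` object.
#' @param burden named numeric vector of per-exon burdens covering every
#'   exon in `expr`.
#' @param config a [pipeline_config()].
#' @return Object of class `critical_exon_matrix`: list with `critical`
#'   (logical exon x sample matrix), `n_samples` (per-exon count of
#'   samples in which it is critical), `expr_thresholds` (per sample) and
#'   `burden_threshold`.
#' @export
critical_exon_matrix <- function(expr, burden, config = pipeline_config()) {
  vals <- expr$values
  if (nrow(vals) < 2)
    stop("expression matrix must have at least 2 exons (percentile ",
         "thresholds are undefined otherwise)", call. = FALSE)
  missing_b <- setdiff(rownames(vals), names(burden))
  if (length(missing_b))
    stop("exon(s) missing a mutation burden: ",
         paste(utils::head(missing_b, 5), collapse = ", "),
         if (length(missing_b) > 5) ", ..." else "", call. = FALSE)
  b <- burden[rownames(vals)]
  pe <- config$expr_percentile / 100
  pb <- config$burden_percentile / 100
  qt <- function(x, p) unname(stats::quantile(x, p,
                                              type = config$percentile_type))
  burden_thr <- qt(b, pb)
  if (config$expr_threshold_scope == "per_sample") {
    expr_thr <- apply(vals, 2, qt, p = pe)
    high <- sweep(vals, 2, expr_thr, `>`)
  } else {
    expr_thr <- stats::setNames(rep(qt(as.vector(vals), pe), ncol(vals)),
                                colnames(vals))
    high <- vals > expr_thr[1]
  }
  crit <- high & (b < burden_thr)
  structure(list(critical = crit,
                 n_samples = rowSums(crit),
                 expr_thresholds = expr_thr,
                 burden_threshold = burden_thr),
            class = "critical_exon_matrix")
}

#' @export
print.critical_exon_matrix <- function(x, ...) {
  cat(sprintf("critical_exon_matrix: %d exons x %d samples, %d exon(s) critical somewhere\n",
              nrow(x$critical), ncol(x$critical), sum(x$n_samples > 0)))
  invisible(x)
}

#' Critical-exon genes
#'
#' A gene is a critical-exon (CE) gene iff at least one of its exons is
#' critical in at least `min_samples` brain samples. The rule is
#' per-exon: two exons critical in 30 samples each do not pool to 60.
#'
#' @param cem a [critical_exon_matrix()] result.
#' @param exon_to_gene named character vector mapping exon ids to gene
#'   symbols (see [exon_to_gene_map()]); must cover every exon.
#' @param min_samples minimum per-exon sample count (default the study's
#'   50 RNA-seq brain samples).
#' @return Character vector of CE gene symbols.
#' @export
ce_genes <- function(cem, exon_to_gene,
                     min_samples = pipeline_config()$min_critical_samples) {
  exons <- names(cem$n_samples)
  if (is.null(exons)) exons <- rownames(cem$critical)
  miss <- setdiff(exons, names(exon_to_gene))
  if (length(miss))
    stop("exon(s) missing from the exon-to-gene map: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  qualifying <- exons[cem$n_samples >= min_samples]
  sort(unique(unname(exon_to_gene[qualifying])))
}

#' Constraint gate: critical exon OR pLI
#'
#' Retains genes that are CE genes or have pLI at or above the threshold
#' (inclusive, `>= 0.9` at defaults). A missing pLI fails the pLI arm —
#' absence of evidence never passes the filter — but such a gene is still
#' retained through the CE arm.
#'
#' @param gene_set character vector of gene symbols.
#' @param ce_set CE gene symbols (from [ce_genes()]).
#' @param pli_map named numeric vector of pLI scores by symbol.
#' @param pli_threshold inclusive lower bound.
#' @return The retained subset of `gene_set`.
#' @export
constraint_filter <- function(gene_set, ce_set, pli_map,
                              pli_threshold = pipeline_config()$pli_threshold) {
  pli <- unname(pli_map[gene_set])
  pass_pli <- !is.na(pli) & pli >= pli_threshold
  pass_ce <- gene_set %in% ce_set
  gene_set[pass_ce | pass_pli]
}

#' Per-gene constraint summary table
#'
#' @param gene_set genes to summarise.
#' @param cem a [critical_exon_matrix()] result.
#' @param exon_to_gene exon id -> symbol map.
#' @param pli_map named pLI vector.
#' @param config a [pipeline_config()].
#' @return Data frame with one row per gene: `symbol`, `best_exon`,
#'   `n_critical_samples` (of the best exon), `is_ce_gene`, `pli`,
#'   `passes_constraint`.
#' @export
constraint_summary <- function(gene_set, cem, exon_to_gene, pli_map,
                               config = pipeline_config()) {
  if (length(gene_set) == 0)
    return(data.frame(symbol = character(), best_exon = character(),
                      n_critical_samples = numeric(),
                      is_ce_gene = logical(), pli = numeric(),
                      passes_constraint = logical()))
  ce <- ce_genes(cem, exon_to_gene, config$min_critical_samples)
  exon_gene <- unname(exon_to_gene[names(cem$n_samples)])
  rows <- lapply(gene_set, function(g) {
    idx <- which(exon_gene == g)
    if (length(idx)) {
      best <- idx[which.max(cem$n_samples[idx])]
      best_exon <- names(cem$n_samples)[best]
      n_crit <- unname(cem$n_samples[best])
    } else {
      best_exon <- NA_character_
      n_crit <- 0
    }
    pli <- unname(pli_map[g])
    data.frame(symbol = g, best_exon = best_exon,
               n_critical_samples = n_crit,
               is_ce_gene = g %in% ce,
               pli = if (is.null(pli)) NA_real_ else pli,
               passes_constraint = length(constraint_filter(
                 g, ce, pli_map, config$pli_threshold)) == 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
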