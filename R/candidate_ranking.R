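## Candidate-gene selection: gene-specific small-CNV recurrence counts and
## the ranking / non-OMIM shortlist rules.

#' Count gene-specific CNVs for one gene
#'
#' The number of distinct case CNVs of size at most `max_size` (1 Mb at
#' defaults) whose interval overlaps at least one CDS base pair of the
#' gene. Counting is at the CNV level: two qualifying CNVs in the same
#' sample both count.
#'
#' @param gene gene symbol.
#' @param calls case CNV calls (already case-filtered).
#' @param models a `gene_models` annotation.
#' @param max_size inclusive size ceiling in bp.
#' @return Non-negative integer count.
#' @export
count_gene_specific_cnvs <- function(gene, calls, models,
                                     max_size = pipeline_config()$candidate_max_cnv_size_bp) {
  small <- calls[calls$size <= max_size, , drop = FALSE]
  ht <- gene_hit_table(small, models)
  sum(ht$symbol == gene)
}

#' Rank candidate genes
#'
#' Builds one record per input gene (its OMIM flag, its gene-specific CNV
#' count and the CNV types seen), orders by descending count with
#' alphabetical tie-break, flags genes with at least two gene-specific
#' CNVs as candidates, and attaches the non-OMIM sublist (the pool from
#' which novel candidates are drawn) as the `"non_omim"` attribute.
#'
#' @param constraint_overlap_genes gene symbols that survived the overlap
#'   and constraint filters.
#' @param calls case CNV calls.
#' @param models a `gene_models` annotation (supplies OMIM flags).
#' @param config a [pipeline_config()].
#' @param membership optional named list of gene-symbol vectors (e.g.
#'   `de_novo_list`, `male_list`, ...); each becomes a logical
#'   `present_in_<name>` column.
#' @return Data frame ordered by rank: `gene`, `is_omim`,
#'   `n_gene_specific_cnvs`, `cnv_types`, `is_candidate`, `rank`, plus
#'   any membership columns; attribute `non_omim` holds the ordered
#'   non-OMIM gene records.
#' @export
rank_candidates <- function(constraint_overlap_genes, calls, models,
                            config = pipeline_config(),
                            membership = NULL) {
  genes <- unique(constraint_overlap_genes)
  small <- calls[calls$size <= config$candidate_max_cnv_size_bp, ,
                 drop = FALSE]
  ht <- gene_hit_table(small, models)
  counts <- table(factor(ht$symbol, levels = genes))
  types <- vapply(genes, function(g) {
    tt <- sort(unique(small$cnv_type[ht$call_idx[ht$symbol == g]]))
    paste(tt, collapse = ",")
  }, "")
  omim <- models$genes$is_omim[match(genes, models$genes$symbol)]
  omim[is.na(omim)] <- FALSE
  out <- data.frame(gene = genes, is_omim = omim,
                    n_gene_specific_cnvs = as.integer(counts),
                    cnv_types = unname(types))
  if (!is.null(membership))
    for (nm in names(membership))
      out[[paste0("present_in_", nm)]] <- out$gene %in% membership[[nm]]
  out <- out[order(-out$n_gene_specific_cnvs, out$gene), , drop = FALSE]
  out$is_candidate <- out$n_gene_specific_cnvs >= 2L
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "non_omim") <- out[!out$is_omim, , drop = FALSE]
  out
}
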