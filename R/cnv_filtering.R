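## CNV-level filters, CNV -> gene extraction via CDS intersection, and the
## control-cohort frequency filter.

#' @noRd
cnv_granges <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(calls$start, calls$end))
}

#' @noRd
cds_granges <- function(models) {
  GenomicRanges::GRanges(models$cds$chrom,
                         IRanges::IRanges(models$cds$start,
                                          models$cds$end))
}

#' Filter CNV calls by size window and stratum labels
#'
#' A call is retained iff `min_cnv_size_bp <= size <= max_cnv_size_bp`
#' (inclusive bounds: calls of exactly 10 kb or 10 Mb are kept) and it
#' matches every requested stratum label. Per-filter exclusion counts are
#' attached as the `"exclusions"` attribute and logged.
#'
#' @param calls CNV call data frame (see [read_cnv_table()]).
#' @param config a [pipeline_config()].
#' @param pathogenicity,inheritance,sex,phenotype,cnv_type optional stratum
#'   restriction; each may be a vector of admissible values, or `NULL` for
#'   no restriction.
#' @return The retained calls, with attribute `exclusions` (named counts).
#' @export
filter_cnvs <- function(calls, config = pipeline_config(),
                        pathogenicity = NULL, inheritance = NULL,
                        sex = NULL, phenotype = NULL, cnv_type = NULL) {
  n0 <- nrow(calls)
  keep <- rep(TRUE, n0)
  excl <- c()
  drop_by <- function(keep, cond, label) {
    lost <- sum(keep & !cond)
    excl[[label]] <<- lost
    keep & cond
  }
  keep <- drop_by(keep, calls$size >= config$min_cnv_size_bp, "too_small")
  keep <- drop_by(keep, calls$size <= config$max_cnv_size_bp, "too_large")
  for (f in c("pathogenicity", "inheritance", "sex", "phenotype",
              "cnv_type")) {
    want <- get(f)
    if (!is.null(want))
      keep <- drop_by(keep, calls[[f]] %in% want, f)
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- unlist(excl)
  ccv_log("cnv_filtering", sprintf("%d/%d calls retained (%s)",
          nrow(out), n0,
          paste(sprintf("%s: -%d", names(excl), unlist(excl)),
                collapse = ", ")))
  if (nrow(out) == 0)
    warning("no CNV calls retained after filtering", call. = FALSE)
  out
}

#' Tabulate genes impacted by each CNV
#'
#' A gene is impacted by a CNV iff the CNV interval overlaps at least one
#' base pair of at least one of the gene's CDS intervals (closed-interval
#' arithmetic); intronic-only overlap does not count.
#'
#' @param calls CNV call data frame.
#' @param models a `gene_models` annotation.
#' @return Data frame (the gene hit table), one row per (call, gene) pair:
#'   `call_idx` (row index into `calls`), `sample_id`, `symbol`, `n_cds`
#'   (CDS intervals overlapped) and `bp` (total overlapped base pairs).
#' @export
gene_hit_table <- function(calls, models) {
  empty <- data.frame(call_idx = integer(), sample_id = character(),
                      symbol = character(), n_cds = integer(),
                      bp = numeric())
  if (nrow(calls) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(cnv_granges(calls),
                                      cds_granges(models))
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov_bp <- pmin(calls$end[qi], models$cds$end[si]) -
    pmax(calls$start[qi], models$cds$start[si]) + 1
  key <- paste(qi, models$cds$symbol[si], sep = "\r")
  agg <- rowsum(cbind(n_cds = rep(1L, length(qi)), bp = ov_bp), key,
                reorder = FALSE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  idx <- as.integer(vapply(parts, `[[`, "", 1L))
  out <- data.frame(call_idx = idx,
                    sample_id = calls$sample_id[idx],
                    symbol = vapply(parts, `[[`, "", 2L),
                    n_cds = as.integer(agg[, "n_cds"]),
                    bp = agg[, "bp"])
  out <- out[order(out$call_idx, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes impacted by a set of CNV calls
#'
#' @inheritParams gene_hit_table
#' @return Character vector of gene symbols with at least one CDS base
#'   pair overlapped by at least one call (possibly empty).
#' @export
genes_impacted <- function(calls, models) {
  sort(unique(gene_hit_table(calls, models)$symbol))
}

#' Per-gene CNV carrier frequency in the control cohort
#'
#' Frequency is the number of distinct control samples carrying at least
#' one CNV that hits the gene's CDS, divided by the total number of
#' control samples; a sample hit by several CNVs counts once. By default
#' deletions and duplications are pooled (conservative removal);
#' `config$control_type_match = TRUE` computes frequencies restricted to
#' `cnv_type`.
#'
#' @param control_calls control-cohort CNV calls.
#' @param models a `gene_models` annotation.
#' @param n_control_samples total control cohort size; defaults to the
#'   number of distinct sample ids in `control_calls` (an undercount if
#'   CNV-free samples are absent from the table, so pass the true total
#'   when known).
#' @param config a [pipeline_config()].
#' @param cnv_type restrict to this type when `config$control_type_match`.
#' @return Object of class `control_frequency`: named numeric frequencies
#'   keyed by gene symbol, with attribute `n_samples` (the denominator).
#' @export
control_gene_frequency <- function(control_calls, models,
                                   n_control_samples = NULL,
                                   config = pipeline_config(),
                                   cnv_type = NULL) {
  if (is.null(n_control_samples))
    n_control_samples <- length(unique(control_calls$sample_id))
  if (n_control_samples <= 0)
    stop("control cohort has zero samples", call. = FALSE)
  if (config$control_type_match && !is.null(cnv_type))
    control_calls <- control_calls[control_calls$cnv_type %in% cnv_type, ,
                                   drop = FALSE]
  ht <- gene_hit_table(control_calls, models)
  carriers <- tapply(ht$sample_id, ht$symbol,
                     function(s) length(unique(s)))
  freq <- as.numeric(carriers) / n_control_samples
  names(freq) <- names(carriers)
  structure(freq, n_samples = n_control_samples,
            class = "control_frequency")
}

#' Remove control-frequent genes from a gene set
#'
#' A gene is removed iff its control frequency is strictly greater than
#' the threshold (`> 0.001` at defaults); genes absent from the frequency
#' map have frequency 0 and are kept.
#'
#' @param gene_set character vector of gene symbols.
#' @param freq_map a [control_gene_frequency()] result (or any named
#'   numeric vector of frequencies).
#' @param threshold strict removal threshold.
#' @return Filtered gene set; removed genes are logged and attached as the
#'   `"removed"` attribute.
#' @export
remove_control_genes <- function(gene_set, freq_map,
                                 threshold = pipeline_config()$control_freq_threshold) {
  f <- unname(freq_map[gene_set])
  f[is.na(f)] <- 0
  removed <- gene_set[f > threshold]
  kept <- gene_set[f <= threshold]
  if (length(removed))
    ccv_log("cnv_filtering", "control filter removed ", length(removed),
            " gene(s): ", paste(utils::head(removed, 10), collapse = ", "),
            if (length(removed) > 10) ", ..." else "")
  attr(kept, "removed") <- removed
  kept
}
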