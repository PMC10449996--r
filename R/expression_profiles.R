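## Developmental-stage, multi-tissue transcriptome, and proteome summaries
## for a gene set.

.stages <- c("prenatal", "early_childhood", "adult")

#' Gene-level expression from exon values
#'
#' The gene-level value of a gene in a sample is the unweighted mean (or
#' median) of its exons' values in that sample.
#'
#' @param expr an `exon_expression` object.
#' @param exon_to_gene named exon id -> symbol map.
#' @param gene_set genes to keep (`NULL` keeps all mapped genes).
#' @param summary `"mean"` or `"median"`.
#' @return Numeric gene x sample matrix.
#' @export
gene_expression <- function(expr, exon_to_gene, gene_set = NULL,
                            summary = c("mean", "median")) {
  summary <- match.arg(summary)
  genes <- unname(exon_to_gene[rownames(expr$values)])
  keep <- !is.na(genes)
  if (!is.null(gene_set)) keep <- keep & genes %in% gene_set
  vals <- expr$values[keep, , drop = FALSE]
  genes <- genes[keep]
  if (nrow(vals) == 0)
    return(matrix(numeric(), 0, ncol(expr$values),
                  dimnames = list(NULL, colnames(expr$values))))
  if (summary == "mean") {
    m <- rowsum(vals, genes) / as.vector(table(genes)[sort(unique(genes))])
  } else {
    m <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i)
      apply(vals[i, , drop = FALSE], 2, stats::median)))
  }
  m[sort(rownames(m)), , drop = FALSE]
}

#' Developmental-stage expression summary
#'
#' Computes each gene's mean expression per developmental stage (mean over
#' samples of that stage of the gene-level values), then per-stage
#' distribution statistics over genes: median, quartiles and IQR whisker
#' bounds (Q1 - IQR, Q3 + IQR).
#'
#' @param expr an `exon_expression` object with stage metadata.
#' @param gene_set genes to profile.
#' @param exon_to_gene named exon id -> symbol map.
#' @param summary exon-to-gene summary, `"mean"` (default) or `"median"`.
#' @return Object of class `stage_summary`: list with `gene_stage_means`
#'   (data frame gene x stage) and `stage_stats` (per stage: `n_samples`,
#'   `q1`, `median`, `q3`, `iqr`, `whisker_low`, `whisker_high` over
#'   genes).
#' @export
stage_summary <- function(expr, gene_set, exon_to_gene,
                          summary = c("mean", "median")) {
  stage <- expr$meta$stage
  n_by_stage <- table(factor(stage, levels = .stages))
  empty <- names(n_by_stage)[n_by_stage == 0]
  if (length(empty))
    stop("no samples for stage(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  gm <- gene_expression(expr, exon_to_gene, gene_set, match.arg(summary))
  means <- matrix(NA_real_, nrow(gm), length(.stages),
                  dimnames = list(rownames(gm), .stages))
  for (st in .stages)
    means[, st] <- rowMeans(gm[, stage == st, drop = FALSE])
  means <- as.data.frame(means)
  stats_rows <- lapply(.stages, function(st) {
    v <- means[[st]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(stage = st, n_samples = as.integer(n_by_stage[[st]]),
               q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
               whisker_low = q[1] - iqr, whisker_high = q[3] + iqr)
  })
  structure(list(gene_stage_means = means,
                 stage_stats = do.call(rbind, stats_rows)),
            class = "stage_summary")
}

#' Compare expression between two developmental stages
#'
#' Two-sided Mann-Whitney U test on per-gene stage means: exact when both
#' groups have at most 8 values and no ties are present, otherwise the
#' normal approximation with tie correction (no continuity correction, so
#' identical distributions give p = 1).
#'
#' @param stage_values_a,stage_values_b numeric vectors (at least 3 values
#'   each).
#' @return The two-sided p-value.
#' @export
compare_stages <- function(stage_values_a, stage_values_b) {
  if (length(stage_values_a) < 3 || length(stage_values_b) < 3)
    stop("compare_stages needs at least 3 values per group", call. = FALSE)
  ties <- anyDuplicated(c(stage_values_a, stage_values_b)) > 0
  exact <- !ties && length(stage_values_a) <= 8 &&
    length(stage_values_b) <= 8
  stats::wilcox.test(stage_values_a, stage_values_b, exact = exact,
                     correct = FALSE)$p.value
}

#' All pairwise stage comparisons
#'
#' @param summ a [stage_summary()] result.
#' @return Data frame with one row per stage pair and its two-sided
#'   Mann-Whitney p-value.
#' @export
compare_all_stages <- function(summ) {
  pairs <- utils::combn(.stages, 2)
  rows <- apply(pairs, 2, function(pr) {
    data.frame(stage_a = pr[1], stage_b = pr[2],
               p_value = compare_stages(summ$gene_stage_means[[pr[1]]],
                                        summ$gene_stage_means[[pr[2]]]))
  })
  do.call(rbind, rows)
}

#' Multi-tissue expression or proteome summary
#'
#' Per-tissue distribution statistics (median, quartiles, IQR whiskers)
#' over the genes of a set, with tissues rank-ordered by decreasing median
#' (ties broken by tissue name, so all-zero tables rank alphabetically).
#'
#' @param values numeric gene x tissue matrix (rownames are symbols).
#' @param gene_set genes to summarise; genes absent from the table are
#'   logged and skipped.
#' @param unit `"spectral_counts"`, `"rpkm"` or `"log2_intensity"`
#'   (annotation only; no transformation is applied).
#' @return Data frame, one row per tissue in rank order: `tissue`, `rank`,
#'   `n_genes`, `q1`, `median`, `q3`, `whisker_low`, `whisker_high`,
#'   `unit`.
#' @export
tissue_summary <- function(values, gene_set,
                           unit = c("spectral_counts", "rpkm",
                                    "log2_intensity")) {
  unit <- match.arg(unit)
  absent <- setdiff(gene_set, rownames(values))
  if (length(absent))
    ccv_log("expression_profiles", "skipping ", length(absent),
            " gene(s) absent from the tissue table")
  present <- intersect(gene_set, rownames(values))
  if (length(present) == 0)
    stop("no genes from the set are present in the tissue table",
         call. = FALSE)
  sub <- values[present, , drop = FALSE]
  rows <- lapply(colnames(sub), function(tis) {
    q <- stats::quantile(sub[, tis], c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(tissue = tis, n_genes = nrow(sub), q1 = q[1],
               median = q[2], q3 = q[3], whisker_low = q[1] - iqr,
               whisker_high = q[3] + iqr, unit = unit)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$median, out$tissue), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("tissue", "rank", setdiff(names(out), c("tissue", "rank")))]
}

#' Expression call from a log2 intensity
#'
#' An exon is called expressed iff its log2-transformed intensity is at
#' least 6; a gene is expressed in a tissue iff any of its exons is.
#'
#' @param log2_value numeric log2 intensity value(s).
#' @param threshold inclusive call threshold.
#' @return Logical vector.
#' @export
expressed_call <- function(log2_value, threshold = 6) {
  log2_value >= threshold
}

#' Gene-level expression call over exon intensities
#'
#' @param exon_log2_values numeric vector of one gene's exon log2
#'   intensities in one tissue.
#' @param threshold inclusive call threshold.
#' @return `TRUE` iff any exon is expressed.
#' @export
gene_expressed <- function(exon_log2_values, threshold = 6) {
  any(expressed_call(exon_log2_values, threshold))
}
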