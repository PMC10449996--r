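# Small in-code fixtures shared across test files.

# A calls data frame in the internal (post-reader) representation.
make_calls <- function(sample_id, chrom = "1", start, end,
                       cnv_type = "deletion",
                       pathogenicity = "pathogenic",
                       inheritance = "de_novo", sex = "male",
                       phenotype = "NDD") {
  df <- data.frame(sample_id = sample_id, chrom = chrom, start = start,
                   end = end, cnv_type = cnv_type,
                   pathogenicity = pathogenicity,
                   inheritance = inheritance, sex = sex,
                   phenotype = phenotype)
  df$size <- df$end - df$start + 1
  df
}

# Tiny annotation: genes given as list(symbol = list of c(start, end)).
make_models <- function(genes, chrom = "1", omim_genes = NULL,
                        pli = NULL) {
  rows <- do.call(rbind, lapply(names(genes), function(g) {
    iv <- do.call(rbind, genes[[g]])
    data.frame(gene_id = g, symbol = g, chrom = chrom, strand = "+",
               start = iv[, 1], end = iv[, 2])
  }))
  gene_models(rows, pli = pli, omim_genes = omim_genes)
}

# Exon expression object from a plain matrix; stages assigned round-robin
# unless given.
make_expr <- function(values, stages = NULL) {
  n <- ncol(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(n))
  if (is.null(stages))
    stages <- rep_len(c("prenatal", "early_childhood", "adult"), n)
  exon_expression(values, data.frame(
    sample_id = colnames(values),
    donor_id = sprintf("D%02d", seq_len(n)),
    brain_region = rep_len(c("OFC", "HIP", "CBC"), n),
    stage = stages))
}

write_tsv_text <- function(text) {
  f <- tempfile(fileext = ".tsv")
  writeLines(text, f)
  f
}

# Independent oracle: hypergeometric upper tail by explicit combinatorial
# summation (never calls phyper).
hyper_tail_oracle <- function(a, size_a, size_b, universe) {
  ks <- a:min(size_a, size_b)
  terms <- vapply(ks, function(k)
    choose(size_a, k) * choose(universe - size_a, size_b - k), 0)
  sum(terms) / choose(universe, size_b)
}

# Independent oracle: per-basepair gene membership for CNV-gene
# intersection.
impacted_oracle <- function(calls, models) {
  hits <- character()
  for (i in seq_len(nrow(calls))) {
    bp <- calls$start[i]:calls$end[i]
    for (g in unique(models$cds$symbol)) {
      cds <- models$cds[models$cds$symbol == g &
                          models$cds$chrom == calls$chrom[i], ,
                        drop = FALSE]
      covered <- FALSE
      for (j in seq_len(nrow(cds)))
        if (any(bp >= cds$start[j] & bp <= cds$end[j])) covered <- TRUE
      if (covered) hits <- c(hits, g)
    }
  }
  sort(unique(hits))
}

# Independent oracle: double-loop critical-exon classifier.
ce_matrix_oracle <- function(values, burden, p = 0.75) {
  bt <- unname(quantile(burden[rownames(values)], p))
  crit <- matrix(FALSE, nrow(values), ncol(values),
                 dimnames = dimnames(values))
  for (s in seq_len(ncol(values))) {
    et <- unname(quantile(values[, s], p))
    for (e in seq_len(nrow(values)))
      crit[e, s] <- values[e, s] > et && burden[rownames(values)[e]] < bt
  }
  crit
}

# Independent oracle: exact two-sided Mann-Whitney by enumeration of all
# group assignments (no ties assumed).
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  mid <- n1 * length(b) / 2
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  mean(abs(us - mid) >= abs(u_obs - mid))
}
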