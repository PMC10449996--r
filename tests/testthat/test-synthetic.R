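test_that("genome generation is deterministic, non-overlapping and bounded", {
  g1 <- generate_genome(n_genes = 50, seed = 1)
  g2 <- generate_genome(n_genes = 50, seed = 1)
  expect_identical(g1, g2)
  g3 <- generate_genome(n_genes = 50, seed = 2)
  expect_false(identical(g1$cds, g3$cds))
  # genes never overlap within a chromosome
  for (ch in unique(g1$cds$chrom)) {
    spans <- do.call(rbind, lapply(split(
      g1$cds[g1$cds$chrom == ch, ], g1$cds$gene_id[g1$cds$chrom == ch]),
      function(d) data.frame(s = min(d$start), e = max(d$end))))
    spans <- spans[order(spans$s), ]
    if (nrow(spans) > 1)
      expect_true(all(spans$s[-1] > spans$e[-nrow(spans)]))
  }
  expect_equal(nrow(generate_genome(n_genes = 0)$genes), 0)
  expect_error(generate_genome(n_genes = 50, chrom_length = 50000,
                               seed = 1), "do not fit")
})

test_that("cohort generation plants shared genes at full penetrance", {
  genome <- generate_genome(n_genes = 80, seed = 4)
  coh <- generate_cohorts(genome, n_ndd = 40, n_ca = 20, n_controls = 50,
                          n_shared_del = 10, n_shared_dup = 5,
                          n_private = 4, n_control_common = 6,
                          penetrance = 1, seed = 4)
  ndd_genes <- genes_impacted(
    coh$ndd[coh$ndd$pathogenicity == "pathogenic", ], genome)
  ca_genes <- genes_impacted(
    coh$ca[coh$ca$pathogenicity == "pathogenic", ], genome)
  expect_true(all(coh$truth$planted_shared_genes %in% ndd_genes))
  expect_true(all(coh$truth$planted_shared_genes %in% ca_genes))
  # planted categories are disjoint
  cats <- list(coh$truth$shared_deletion_genes,
               coh$truth$shared_duplication_genes,
               coh$truth$planted_private_genes$NDD,
               coh$truth$planted_private_genes$CA,
               coh$truth$planted_control_common_genes)
  expect_equal(length(unique(unlist(cats))), length(unlist(cats)))
  # case CNV sizes respect the analysis window
  expect_true(all(coh$ndd$size >= 10000 & coh$ndd$size <= 1e7))
  expect_error(generate_cohorts(genome, penetrance = 1.2),
               "penetrance")
})

test_that("control-common genes exceed the frequency threshold", {
  genome <- generate_genome(n_genes = 80, seed = 6)
  coh <- generate_cohorts(genome, n_ndd = 20, n_ca = 10,
                          n_controls = 400, n_shared_del = 5,
                          n_shared_dup = 3, n_private = 2,
                          n_control_common = 10,
                          control_recurrence = 0.05, seed = 6)
  freq <- control_gene_frequency(coh$control, genome,
                                 n_control_samples = 400)
  f <- freq[coh$truth$planted_control_common_genes]
  # binomial expectation 0.05; all well above thresholds below 0.02
  expect_true(all(f > 0.02))
})

test_that("same seed gives byte-identical generated tables", {
  genome <- generate_genome(n_genes = 60, seed = 9)
  a <- generate_cohorts(genome, n_ndd = 20, n_ca = 10, n_controls = 30,
                        n_shared_del = 5, n_shared_dup = 3,
                        n_private = 2, n_control_common = 4, seed = 9)
  b <- generate_cohorts(genome, n_ndd = 20, n_ca = 10, n_controls = 30,
                        n_shared_del = 5, n_shared_dup = 3,
                        n_private = 2, n_control_common = 4, seed = 9)
  expect_identical(a$ndd, b$ndd)
  expect_identical(a$control, b$control)
  e1 <- generate_expression_and_burden(genome, a$truth, n_per_stage = 4,
                                       seed = 9)
  e2 <- generate_expression_and_burden(genome, a$truth, n_per_stage = 4,
                                       seed = 9)
  expect_identical(e1$expr$values, e2$expr$values)
  expect_identical(e1$burden, e2$burden)
  g1 <- generate_gmt(genome, a$truth, n_pathways = 10,
                     size_range = c(51, 55), planted_size = 55, seed = 9)
  expect_identical(g1, generate_gmt(genome, a$truth, n_pathways = 10,
                                    size_range = c(51, 55),
                                    planted_size = 55, seed = 9))
  expect_error(generate_gmt(genome, a$truth, planted_size = 500),
               "exceeds the gene count")
})

test_that("expression generator plants constraint structure", {
  genome <- generate_genome(n_genes = 100, seed = 10)
  coh <- generate_cohorts(genome, n_ndd = 20, n_ca = 10, n_controls = 30,
                          n_shared_del = 10, n_shared_dup = 5,
                          n_private = 3, n_control_common = 5, seed = 10)
  eb <- generate_expression_and_burden(genome, coh$truth,
                                       n_per_stage = 10, seed = 10)
  con <- coh$truth$planted_constraint_genes
  expect_true(all(eb$pli[con] >= 0.9))
  expect_true(all(eb$pli[setdiff(names(eb$pli), con)] < 0.9))
  # constraint exons carry lower burden on average
  is_con <- unname(exon_to_gene_map(genome)[names(eb$burden)]) %in% con
  expect_lt(mean(eb$burden[is_con]), mean(eb$burden[!is_con]))
  # planted prenatal > adult > childhood ordering for constraint genes
  summ <- stage_summary(eb$expr, con, exon_to_gene_map(genome))
  m <- colMeans(summ$gene_stage_means)
  expect_gt(m[["prenatal"]], m[["adult"]])
  expect_gt(m[["adult"]], m[["early_childhood"]])
})

test_that("generated files parse cleanly through every reader", {
  dir <- tempfile("sim")
  sim <- suppressMessages(
    simulate_study(dir, seed = 3, n_genes = 250, n_ndd = 20, n_ca = 10,
                   n_controls = 30, n_shared_del = 5, n_shared_dup = 3,
                   n_private = 2, n_control_common = 4))
  ndd <- read_cnv_table(sim$ndd_cnvs)
  expect_gt(nrow(ndd), 0)
  models <- read_gene_models(sim$gene_models, "gtf")
  expect_equal(nrow(models$genes), 250)
  expr <- read_expression_matrix(sim$expression, sim$expression_meta)
  expect_equal(ncol(expr$values), 60)
  burden <- read_exon_burden(sim$burden)
  expect_setequal(names(burden), rownames(expr$values))
  pli <- read_pli(sim$pli)
  expect_equal(length(pli), 250)
  gmt <- read_gmt(sim$gmt)
  expect_equal(length(gmt), 100)
  # ground truth round-trips through JSON
  truth <- read_ground_truth(sim$ground_truth)
  expect_equal(truth$planted_shared_genes,
               sim$truth$planted_shared_genes)
  expect_equal(truth$planted_private_genes$NDD,
               sim$truth$planted_private_genes$NDD)
  # exon ids in the matrix map onto annotation CDS ids
  expect_true(all(rownames(expr$values) %in% models$cds$cds_id))
})
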