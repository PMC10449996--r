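test_that("size window is inclusive at 10 kb and 10 Mb", {
  calls <- make_calls(paste0("S", 1:4), start = 1,
                      end = c(9999, 10000, 1e7, 1e7 + 1))
  kept <- filter_cnvs(calls, pipeline_config())
  expect_equal(kept$sample_id, c("S2", "S3"))
  excl <- attr(kept, "exclusions")
  expect_equal(unname(excl[c("too_small", "too_large")]), c(1, 1))
})

test_that("filtering is idempotent and monotone in the size window", {
  set.seed(11)
  calls <- make_calls(paste0("S", 1:50), start = 1,
                      end = round(10^runif(50, 3, 7.5)))
  cfg <- pipeline_config()
  once <- filter_cnvs(calls, cfg)
  twice <- filter_cnvs(once, cfg)
  attr(once, "exclusions") <- attr(twice, "exclusions") <- NULL
  expect_equal(twice, once)
  narrow <- pipeline_config(min_cnv_size_bp = 5e4, max_cnv_size_bp = 5e6)
  kept_narrow <- filter_cnvs(calls, narrow)
  expect_true(all(kept_narrow$sample_id %in% once$sample_id))
})

test_that("stratum labels restrict retained calls", {
  calls <- make_calls(c("S1", "S2"), start = 1, end = 20000,
                      pathogenicity = c("pathogenic", "VUS"),
                      sex = c("male", "female"))
  kept <- filter_cnvs(calls, pipeline_config(),
                      pathogenicity = "pathogenic", sex = "male")
  expect_equal(kept$sample_id, "S1")
  expect_warning(filter_cnvs(calls, pipeline_config(), sex = "male",
                             pathogenicity = "VUS"),
                 "no CNV calls retained")
})

test_that("genes_impacted requires >= 1 bp of CDS overlap", {
  models <- make_models(list(GA = list(c(150, 300)),
                             GB = list(c(400, 450), c(600, 650)),
                             GC = list(c(200, 250))))
  # overlap of 51 bp with GA's CDS
  ht <- gene_hit_table(make_calls("S1", start = 100, end = 200), models)
  expect_equal(ht$symbol[ht$symbol == "GA"], "GA")
  expect_equal(ht$bp[ht$symbol == "GA"], 51)
  # CNV inside GB's intron only: excluded
  expect_equal(genes_impacted(make_calls("S1", start = 460, end = 590),
                              models),
               character(0))
  # closed intervals: single-bp touch counts
  ht2 <- gene_hit_table(make_calls("S1", start = 100, end = 200),
                        models)
  expect_true("GC" %in% ht2$symbol)
  expect_equal(ht2$bp[ht2$symbol == "GC"], 1)
})

test_that("genes_impacted matches the per-basepair oracle on random genomes", {
  set.seed(101)
  for (rep in 1:8) {
    n_genes <- sample(3:8, 1)
    genes <- list()
    pos <- 1
    for (g in seq_len(n_genes)) {
      k <- sample(1:3, 1)
      iv <- list()
      for (j in seq_len(k)) {
        start <- pos + sample(50:300, 1)
        end <- start + sample(20:200, 1)
        iv[[j]] <- c(start, end)
        pos <- end
      }
      genes[[sprintf("G%02d", g)]] <- iv
      pos <- pos + sample(100:500, 1)
    }
    models <- make_models(genes)
    starts <- sample(seq_len(pos), 5)
    calls <- make_calls(paste0("S", 1:5), start = starts,
                        end = starts + sample(50:2000, 5, replace = TRUE))
    expect_equal(genes_impacted(calls, models),
                 impacted_oracle(calls, models))
  }
})

test_that("control frequency counts distinct carrier samples", {
  models <- make_models(list(GA = list(c(1000, 2000))))
  # 10 carriers of 9692 -> just above the 0.001 threshold
  calls <- make_calls(sprintf("C%02d", 1:10), start = 900, end = 2100,
                      phenotype = "control", pathogenicity = "benign",
                      inheritance = "unknown")
  freq <- control_gene_frequency(calls, models,
                                 n_control_samples = 9692)
  expect_equal(unname(freq["GA"]), 10 / 9692)
  # a sample hit twice counts once
  calls2 <- make_calls(c("C1", "C1"), start = c(900, 950),
                       end = c(2100, 2200), phenotype = "control")
  freq2 <- control_gene_frequency(calls2, models,
                                  n_control_samples = 100)
  expect_equal(unname(freq2["GA"]), 0.01)
  expect_error(control_gene_frequency(calls2, models,
                                      n_control_samples = 0),
               "zero samples")
})

test_that("control-gene removal uses a strict threshold", {
  freq <- c(GA = 10 / 9692, GB = 9 / 9692, GC = 0)
  kept <- suppressMessages(
    remove_control_genes(c("GA", "GB", "GC", "GD"), freq, 0.001))
  expect_equal(as.character(kept), c("GB", "GC", "GD"))  # 10/9692 > 0.001
  expect_equal(attr(kept, "removed"), "GA")   # 9/9692 < 0.001 retained
  # empty frequency map leaves the set unchanged
  expect_equal(as.character(remove_control_genes(c("GA", "GB"),
                                                 numeric(), 0.001)),
               c("GA", "GB"))
})
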