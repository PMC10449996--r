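test_that("the four-exon worked example classifies exactly one exon", {
  vals <- matrix(c(1, 2, 3, 10), ncol = 1,
                 dimnames = list(paste0("E", 1:4), "S1"))
  burden <- c(E1 = 5, E2 = 1, E3 = 2, E4 = 3)
  cem <- critical_exon_matrix(make_expr(vals, stages = "prenatal"),
                              burden)
  # linear-interpolation percentiles: expr 4.75, burden 3.5
  expect_equal(unname(cem$expr_thresholds), 4.75)
  expect_equal(unname(cem$burden_threshold), 3.5)
  expect_equal(unname(cem$critical[, 1]),
               c(FALSE, FALSE, FALSE, TRUE))
})

test_that("strict inequalities: uniform expression yields no critical exon", {
  vals <- matrix(5, nrow = 4, ncol = 3,
                 dimnames = list(paste0("E", 1:4), NULL))
  burden <- c(E1 = 0, E2 = 0, E3 = 0, E4 = 0)
  cem <- critical_exon_matrix(make_expr(vals), burden)
  expect_false(any(cem$critical))
})

test_that("an exon at or above the burden threshold is never critical", {
  vals <- matrix(c(1, 1, 1, 100), nrow = 4, ncol = 2,
                 dimnames = list(paste0("E", 1:4), NULL))
  burden <- c(E1 = 0, E2 = 0, E3 = 0, E4 = 50)
  cem <- critical_exon_matrix(make_expr(vals), burden)
  expect_false(any(cem$critical["E4", ]))
})

test_that("missing burdens and tiny matrices are rejected", {
  vals <- matrix(1:4, 2, 2, dimnames = list(c("E1", "E2"), NULL))
  expect_error(critical_exon_matrix(make_expr(vals), c(E1 = 1)), "E2")
  one <- matrix(1:3, 1, 3, dimnames = list("E1", NULL))
  expect_error(critical_exon_matrix(make_expr(one), c(E1 = 1)),
               "at least 2 exons")
})

test_that("classifier equals the double-loop oracle on random matrices", {
  set.seed(202)
  for (rep in 1:50) {
    vals <- matrix(rlnorm(100), nrow = 20, ncol = 5,
                   dimnames = list(sprintf("E%02d", 1:20),
                                   sprintf("S%02d", 1:5)))
    burden <- setNames(rpois(20, 5), rownames(vals))
    cem <- critical_exon_matrix(make_expr(vals), burden)
    expect_identical(cem$critical, ce_matrix_oracle(vals, burden))
    expect_identical(cem$n_samples, rowSums(cem$critical))
  }
})

test_that("global expression-threshold variant uses one matrix-wide cut", {
  vals <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), nrow = 4,
                 dimnames = list(paste0("E", 1:4), NULL))
  burden <- c(E1 = 0, E2 = 0, E3 = 0, E4 = 100)
  cfg <- pipeline_config(expr_threshold_scope = "global")
  cem <- critical_exon_matrix(make_expr(vals), burden, cfg)
  thr <- unname(quantile(as.vector(vals), 0.75))  # 22.5
  expect_true(all(cem$expr_thresholds == thr))
  low_burden <- burden < unname(quantile(burden, 0.75))
  expect_identical(unname(cem$critical),
                   unname((vals > thr) & low_burden))
})

test_that("ce_genes applies the per-exon sample threshold without pooling", {
  crit <- matrix(FALSE, 3, 60,
                 dimnames = list(c("E1", "E2", "E3"),
                                 sprintf("S%02d", 1:60)))
  crit["E1", 1:50] <- TRUE   # exactly at the threshold
  crit["E2", 1:30] <- TRUE   # two exons of one gene, 30 samples each:
  crit["E3", 31:60] <- TRUE  # distinct samples must NOT pool to 60
  cem <- structure(list(critical = crit, n_samples = rowSums(crit)),
                   class = "critical_exon_matrix")
  map <- c(E1 = "GA", E2 = "GB", E3 = "GB")
  expect_equal(ce_genes(cem, map, 50), "GA")
  # boundary: 49 samples is not enough
  crit["E1", 50] <- FALSE
  cem$n_samples <- rowSums(crit)
  expect_equal(ce_genes(cem, map, 50), character(0))
})

test_that("ce_genes is monotone in min_samples", {
  set.seed(5)
  crit <- matrix(runif(300) < 0.5, 5, 60,
                 dimnames = list(paste0("E", 1:5), NULL))
  cem <- structure(list(critical = crit, n_samples = rowSums(crit)),
                   class = "critical_exon_matrix")
  map <- setNames(paste0("G", 1:5), paste0("E", 1:5))
  prev <- ce_genes(cem, map, 1)
  for (ms in seq(5, 60, by = 5)) {
    cur <- ce_genes(cem, map, ms)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("constraint gate is CE OR pLI with inclusive pLI and strict missing", {
  pli <- c(GA = 0.90, GB = 0.89)
  expect_equal(constraint_filter(c("GA", "GB"), character(), pli, 0.9),
               "GA")
  # missing pLI fails the pLI arm but CE membership still retains
  expect_equal(constraint_filter(c("GC"), c("GC"), pli, 0.9), "GC")
  expect_equal(constraint_filter(c("GC"), character(), pli, 0.9),
               character(0))
})

test_that("constraint_summary reports best exon and gates consistently", {
  vals <- matrix(c(1, 2, 3, 10), ncol = 1,
                 dimnames = list(paste0("E", 1:4), "S1"))
  burden <- c(E1 = 5, E2 = 1, E3 = 2, E4 = 3)
  cem <- critical_exon_matrix(make_expr(vals, stages = "prenatal"),
                              burden)
  map <- c(E1 = "GA", E2 = "GA", E3 = "GB", E4 = "GB")
  summ <- constraint_summary(c("GA", "GB"), cem, map,
                             c(GA = 0.95, GB = 0.1),
                             pipeline_config(min_critical_samples = 1))
  expect_equal(summ$best_exon, c("E1", "E4"))
  expect_equal(summ$is_ce_gene, c(FALSE, TRUE))
  expect_equal(summ$passes_constraint, c(TRUE, TRUE))
})
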