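test_that("closed-form overlap cases reproduce", {
  # identical sets: all draws are successes, p = 1/C(10,3)
  res <- overlap_test(letters[1:3], letters[1:3], universe = 10)
  expect_equal(res$a, 3)
  expect_equal(res$p_value, 1 / choose(10, 3))
  expect_identical(res$odds_ratio, Inf)
  # disjoint sets filling the universe: a = 0 so the upper tail is 1
  res2 <- overlap_test(c("a", "b"), c("c", "d"), universe = 4)
  expect_equal(res2$p_value, 1)
  expect_identical(res2$odds_ratio, 0)
})

test_that("p-value matches the combinatorial tail oracle", {
  # |A| = |B| = 10, a = 5, universe = 100
  set_a <- paste0("g", 1:10)
  set_b <- c(paste0("g", 1:5), paste0("h", 1:5))
  res <- overlap_test(set_a, set_b, universe = 100)
  expect_equal(res$a, 5)
  expect_equal(res$p_value, hyper_tail_oracle(5, 10, 10, 100))
})

test_that("overlap_test agrees with fisher.test one-sided", {
  set.seed(3)
  for (i in 1:20) {
    universe <- sample(20:200, 1)
    pool <- paste0("g", seq_len(universe))
    a <- sample(pool, sample(universe, 1))
    b <- sample(pool, sample(universe, 1))
    res <- overlap_test(a, b, universe)
    ft <- fisher.test(matrix(c(res$a, res$b, res$c, res$d), 2),
                      alternative = "greater")
    expect_equal(res$p_value, ft$p.value, tolerance = 1e-12)
  }
})

test_that("counts sum to the universe and errors fire", {
  res <- overlap_test(paste0("g", 1:7), paste0("g", 4:12), universe = 30)
  expect_equal(res$a + res$b + res$c + res$d, 30)
  expect_error(overlap_test(paste0("g", 1:7), paste0("g", 4:12),
                            universe = 10), "universe")
  expect_error(overlap_test("a", "b", universe = 0), "positive")
})

test_that("p-value is non-increasing in the intersection at fixed margins", {
  universe <- 60
  p <- vapply(0:10, function(a) {
    set_a <- c(paste0("s", seq_len(a), recycle0 = TRUE),
               paste0("a", seq_len(10 - a), recycle0 = TRUE))
    set_b <- c(paste0("s", seq_len(a), recycle0 = TRUE),
               paste0("b", seq_len(10 - a), recycle0 = TRUE))
    overlap_test(set_a, set_b, universe)$p_value
  }, 0)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("conditional-MLE odds ratio variant is exposed", {
  res <- overlap_test(paste0("g", 1:10),
                      c(paste0("g", 1:5), paste0("h", 1:5)),
                      universe = 100, or_method = "cmle")
  ft <- fisher.test(matrix(c(5, 5, 5, 85), 2), alternative = "greater")
  expect_equal(res$odds_ratio, unname(ft$estimate))
})

test_that("underflowing p-values are formatted as a floor", {
  expect_equal(format_p(1e-310), "< 1e-300")
  expect_false(grepl("<", format_p(0.01)))
})

test_that("the stratified battery recovers planted structure", {
  genes <- list()
  for (i in 1:60)
    genes[[sprintf("G%02d", i)]] <- list(c(i * 50000, i * 50000 + 500))
  models <- make_models(genes)
  span <- function(i) c(i * 50000 - 2000, i * 50000 + 12000)
  mk <- function(idx, phenotype, sex, type = "deletion",
                 pathogenicity = "pathogenic") {
    st <- vapply(idx, function(i) span(i)[1], 0)
    en <- vapply(idx, function(i) span(i)[2], 0)
    make_calls(paste0(phenotype, idx), start = st, end = en,
               cnv_type = type, pathogenicity = pathogenicity,
               sex = sex, phenotype = phenotype)
  }
  # 30 shared genes + 10 private per cohort, universe 60
  ndd <- rbind(mk(1:30, "NDD", "male"), mk(31:40, "NDD", "female"))
  ca <- rbind(mk(1:30, "CA", "female"), mk(41:50, "CA", "male"))
  bat <- suppressMessages(suppressWarnings(
    stratified_overlap_battery(ndd, ca, models,
                               config = pipeline_config(
                                 universe_size = 1000))))
  pooled <- bat[bat$sex == "pooled" & bat$pathogenicity == "pathogenic" &
                  bat$cnv_type == "deletion" & bat$inheritance == "all", ]
  expect_equal(pooled$a, 30)
  expect_lt(pooled$p_value, 1e-6)
  expect_equal(pooled$universe, 1000)
  # disjoint cohorts: OR = 0 in every populated stratum
  bat0 <- suppressMessages(suppressWarnings(
    stratified_overlap_battery(mk(1:10, "NDD", "male"),
                               mk(21:30, "CA", "male"), models)))
  pop <- bat0[!bat0$degenerate, ]
  expect_true(all(pop$odds_ratio == 0))
  # identical cohorts: OR = infinite in every populated stratum
  bat1 <- suppressMessages(suppressWarnings(
    stratified_overlap_battery(mk(1:10, "NDD", "male"),
                               mk(1:10, "CA", "male"), models)))
  pop1 <- bat1[!bat1$degenerate, ]
  expect_gt(nrow(pop1), 0)
  expect_true(all(is.infinite(pop1$odds_ratio)))
  # empty strata are flagged degenerate, not errors
  expect_true(any(bat0$degenerate))
  expect_true(all(bat0$a[bat0$degenerate] == 0))
})
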