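## Cross-phenotype gene-set overlap statistics: one-sided Fisher's exact
## test (hypergeometric upper tail) with the sample cross-product odds
## ratio, and the stratified battery applied to two case cohorts.

#' One-sided gene-set overlap test
#'
#' Tests enrichment of the intersection of two gene sets against a
#' hypergeometric null on a finite gene universe. With `a = |A intersect
#' B|`, `b = |A \\ B|`, `c = |B \\ A|`, `d = universe - |A union B|`, the
#' p-value is `P(X >= a)` for `X` hypergeometric with population
#' `universe`, `|A|` successes and `|B|` draws (equivalently a one-sided
#' Fisher's exact test, alternative "greater"). The default odds ratio is
#' the sample cross-product `(a*d)/(b*c)` with the conventions 0 when
#' `a = 0` and `Inf` when `a > 0` and `b*c = 0`; `or_method = "cmle"`
#' returns the conditional-MLE estimate from [stats::fisher.test()]
#' instead.
#'
#' @param set_a,set_b character vectors (duplicates ignored).
#' @param universe positive integer, at least `|A union B|`.
#' @param or_method `"sample"` or `"cmle"`.
#' @return Object of class `overlap_result`: a one-row data frame with
#'   columns `a`, `b`, `c`, `d`, `p_value`, `odds_ratio`, `universe` and
#'   `degenerate` (TRUE when either set is empty).
#' @examples
#' overlap_test(letters[1:3], letters[1:3], universe = 10)  # p = 1/120
#' @export
overlap_test <- function(set_a, set_b, universe,
                         or_method = c("sample", "cmle")) {
  or_method <- match.arg(or_method)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- as.numeric(universe)
  if (length(universe) != 1L || is.na(universe) || universe < 1)
    stop("universe must be a positive integer", call. = FALSE)
  n_union <- length(union(set_a, set_b))
  if (universe < n_union)
    stop(sprintf("universe (%d) smaller than |A union B| (%d)",
                 universe, n_union), call. = FALSE)
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  c <- length(set_b) - a
  d <- universe - a - b - c
  p <- stats::phyper(a - 1, m = a + b, n = c + d, k = a + c,
                     lower.tail = FALSE)
  or <- if (or_method == "cmle") {
    stats::fisher.test(matrix(c(a, b, c, d), nrow = 2),
                       alternative = "greater")$estimate[[1]]
  } else if (a == 0) {
    0
  } else if (b * c == 0) {
    Inf
  } else {
    (a * d) / (b * c)
  }
  structure(data.frame(a = a, b = b, c = c, d = d, p_value = p,
                       odds_ratio = or, universe = universe,
                       degenerate = length(set_a) == 0 ||
                         length(set_b) == 0),
            class = c("overlap_result", "data.frame"))
}

#' Format a p-value, flooring underflow
#'
#' Probabilities below double-precision underflow are reported as
#' `"< 1e-300"` rather than 0.
#'
#' @param p numeric p-value(s).
#' @return Character representation.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-300, "< 1e-300", format(p, digits = 3))
}

#' @noRd
resolve_universe <- function(config, models) {
  if (identical(config$universe_size, "annotation")) {
    nrow(models$genes)
  } else {
    config$universe_size
  }
}

#' Stratified cross-cohort overlap battery
#'
#' For every stratum in \{male, female, pooled\} x \{pathogenic, VUS\} x
#' \{deletion, duplication\} x \{all, de novo\}, both cohorts' calls are
#' size- and stratum-filtered, genes are extracted by CDS intersection,
#' control-frequent genes are removed, and the two gene sets are compared
#' with [overlap_test()]. A stratum where either side has no genes is
#' reported with `a = 0` and `degenerate = TRUE`, never as an error.
#'
#' @param ndd_calls,ca_calls CNV call tables for the two case cohorts.
#' @param models a `gene_models` annotation.
#' @param freq_map control frequencies from [control_gene_frequency()]
#'   (`NULL` skips the control filter).
#' @param config a [pipeline_config()].
#' @param keep_gene_sets if `TRUE`, the per-stratum gene sets are attached
#'   as the `"gene_sets"` attribute.
#' @return Data frame with one row per stratum: `sex`, `pathogenicity`,
#'   `cnv_type`, `inheritance`, counts `a`-`d`, `p_value`, `odds_ratio`,
#'   `universe`, `degenerate`.
#' @export
stratified_overlap_battery <- function(ndd_calls, ca_calls, models,
                                       freq_map = NULL,
                                       config = pipeline_config(),
                                       keep_gene_sets = FALSE) {
  universe <- resolve_universe(config, models)
  grid <- expand.grid(sex = c("male", "female", "pooled"),
                      pathogenicity = c("pathogenic", "VUS"),
                      cnv_type = c("deletion", "duplication"),
                      inheritance = c("all", "de_novo"),
                      stringsAsFactors = FALSE)
  gene_sets <- vector("list", nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sex <- if (g$sex == "pooled") NULL else g$sex
    inh <- if (g$inheritance == "all") NULL else g$inheritance
    extract <- function(calls) {
      kept <- suppressWarnings(
        filter_cnvs(calls, config, pathogenicity = g$pathogenicity,
                    cnv_type = g$cnv_type, sex = sex, inheritance = inh))
      gs <- genes_impacted(kept, models)
      if (!is.null(freq_map))
        gs <- remove_control_genes(gs, freq_map,
                                   config$control_freq_threshold)
      as.character(gs)
    }
    set_a <- extract(ndd_calls)
    set_b <- extract(ca_calls)
    gene_sets[[i]] <<- list(ndd = set_a, ca = set_b)
    res <- overlap_test(set_a, set_b, universe,
                        or_method = config$or_method)
    cbind(g, as.data.frame(res), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_gene_sets) {
    names(gene_sets) <- apply(grid, 1, paste, collapse = ".")
    attr(out, "gene_sets") <- gene_sets
  }
  out
}
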