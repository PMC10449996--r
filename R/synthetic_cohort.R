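## Seeded generator of every input the pipeline consumes, with planted
## ground truth: two case cohorts sharing constraint genes hit by
## overlapping pathogenic CNVs, a control pool carrying common CNVs, a
## brain expression matrix in which planted constraint genes are
## prenatally upregulated with low mutation burden and high pLI, and a GMT
## collection containing one pathway overloaded with planted genes.

.brain_regions <- c("OFC", "DFC", "VFC", "MFC", "M1C", "S1C", "IPC",
                    "A1C", "STC", "ITC", "V1C", "HIP", "AMY", "STR",
                    "MD", "CBC")

## Run code under a fixed seed without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping genes round-robin across chromosomes 1-22 and X,
#' each with 2-10 CDS intervals separated by introns and a wide
#' intergenic gap (so a planted CNV padded around one gene never touches
#' its neighbours). Deterministic under `seed`.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range (length 2) of CDS intervals per
#'   gene.
#' @param chrom_length optional single contig length (bp); an error is
#'   raised if the layout does not fit.
#' @param gene_gap intergenic spacing in bp.
#' @param seed RNG seed.
#' @return A `gene_models` object (pLI unset; see
#'   [generate_expression_and_burden()]).
#' @export
generate_genome <- function(n_genes = 500, exons_per_gene = c(2, 10),
                            chrom_length = NULL, gene_gap = 40000,
                            seed = 1) {
  if (n_genes == 0) {
    return(structure(list(
      genes = data.frame(gene_id = character(), symbol = character(),
                         chrom = character(), strand = character(),
                         is_omim = logical(), pli = numeric()),
      cds = data.frame(cds_id = character(), gene_id = character(),
                       symbol = character(), chrom = character(),
                       strand = character(), start = numeric(),
                       end = numeric())), class = "gene_models"))
  }
  with_seed(seed, {
    chroms <- c(as.character(1:22), "X")
    sym <- sprintf("G%04d", seq_len(n_genes))
    chrom <- chroms[((seq_len(n_genes) - 1) %% length(chroms)) + 1]
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    pos <- stats::setNames(rep(1, length(chroms)), chroms)
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      k <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1)
      ex_len <- sample(80:300, k, replace = TRUE)
      intr <- if (k > 1) sample(200:2000, k - 1, replace = TRUE) else
        integer()
      start <- pos[[chrom[i]]] + gene_gap
      starts <- start + cumsum(c(0, ex_len[-k] + intr))
      ends <- starts + ex_len - 1
      pos[[chrom[i]]] <- ends[k]
      if (!is.null(chrom_length) && ends[k] > chrom_length)
        stop("genes do not fit chromosome ", chrom[i], " of length ",
             chrom_length, call. = FALSE)
      rows[[i]] <- data.frame(gene_id = sym[i], symbol = sym[i],
                              chrom = chrom[i], strand = strand[i],
                              start = starts, end = ends)
    }
    gene_models(do.call(rbind, rows))
  })
}

#' @noRd
gene_span <- function(models, symbols) {
  cds <- models$cds[models$cds$symbol %in% symbols, , drop = FALSE]
  agg <- data.frame(symbol = symbols,
                    chrom = cds$chrom[match(symbols, cds$symbol)],
                    start = tapply(cds$start, cds$symbol, min)[symbols],
                    end = tapply(cds$end, cds$symbol, max)[symbols])
  rownames(agg) <- NULL
  agg
}

## One planted CNV per (gene, sample): the gene span padded on each side so
## the total size clears 10 kb but stays well inside the intergenic gap.
#' @noRd
plant_cnv <- function(span_row, sample_id, sex, cnv_type, pathogenicity,
                      inheritance, phenotype) {
  pad <- sample(2000:8000, 2, replace = TRUE)
  start <- max(1, span_row$start - pad[1])
  end <- span_row$end + pad[2]
  if (end - start + 1 < 10000) end <- start + 9999
  data.frame(sample_id = sample_id, chrom = span_row$chrom,
             start = start, end = end, cnv_type = cnv_type,
             pathogenicity = pathogenicity, inheritance = inheritance,
             sex = sex, phenotype = phenotype,
             size = end - start + 1)
}

#' Generate synthetic case and control cohorts with planted ground truth
#'
#' Plants a set of shared genes hit by pathogenic de novo CNVs in both
#' case cohorts (deletions and duplications in separate gene sets),
#' cohort-private genes hit in one cohort only, and control-common genes
#' hit recurrently in the control pool so their carrier frequency exceeds
#' the 0.001 filter. Background noise CNVs of mixed pathogenicity are
#' added on top. Deterministic under `seed`.
#'
#' @param genome a `gene_models` object from [generate_genome()].
#' @param n_ndd,n_ca,n_controls cohort sizes.
#' @param n_shared_del,n_shared_dup planted genes shared by both cohorts
#'   via pathogenic deletions / duplications.
#' @param n_private planted genes private to each cohort.
#' @param n_control_common genes recurrently hit in controls.
#' @param penetrance probability in \[0, 1\] that a planted gene is hit in
#'   a given cohort.
#' @param control_recurrence per-sample carrier probability of each
#'   control-common gene.
#' @param noise_rate per-case-sample probability of one background CNV.
#' @param seed RNG seed.
#' @return List with CNV call data frames `ndd`, `ca`, `control`, a
#'   `samples` table (`sample_id`, `phenotype`, `sex`, `site`) and
#'   `truth` (class `ground_truth`): planted gene categories and the seed.
#' @export
generate_cohorts <- function(genome, n_ndd = 300, n_ca = 150,
                             n_controls = 400, n_shared_del = 30,
                             n_shared_dup = 12, n_private = 10,
                             n_control_common = 25, penetrance = 1,
                             control_recurrence = 0.05, noise_rate = 0.1,
                             seed = 1) {
  if (penetrance < 0 || penetrance > 1)
    stop("penetrance must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    syms <- genome$genes$symbol
    need <- n_shared_del + n_shared_dup + 2 * n_private + n_control_common
    if (need > length(syms))
      stop("genome too small for the requested planted gene categories",
           call. = FALSE)
    picked <- sample(syms, need)
    shared_del <- picked[seq_len(n_shared_del)]
    shared_dup <- picked[n_shared_del + seq_len(n_shared_dup)]
    off <- n_shared_del + n_shared_dup
    private_ndd <- picked[off + seq_len(n_private)]
    private_ca <- picked[off + n_private + seq_len(n_private)]
    control_common <- picked[off + 2 * n_private + seq_len(n_control_common)]

    samples <- data.frame(
      sample_id = c(sprintf("NDD%04d", seq_len(n_ndd)),
                    sprintf("CA%04d", seq_len(n_ca)),
                    sprintf("CTRL%04d", seq_len(n_controls))),
      phenotype = c(rep("NDD", n_ndd), rep("CA", n_ca),
                    rep("control", n_controls)),
      sex = sample(c("male", "female"), n_ndd + n_ca + n_controls,
                   replace = TRUE),
      site = sample(c("site_A", "site_B"), n_ndd + n_ca + n_controls,
                    replace = TRUE))
    sex_of <- stats::setNames(samples$sex, samples$sample_id)

    plant_set <- function(gene_syms, cohort_ids, cnv_type, phenotype,
                          pathogenicity = "pathogenic",
                          inheritance = "de_novo") {
      hit <- gene_syms[stats::runif(length(gene_syms)) <= penetrance]
      if (!length(hit)) return(NULL)
      spans <- gene_span(genome, hit)
      do.call(rbind, lapply(seq_along(hit), function(i) {
        sid <- sample(cohort_ids, 1)
        plant_cnv(spans[i, ], sid, sex_of[[sid]], cnv_type, pathogenicity,
                  inheritance, phenotype)
      }))
    }
    ndd_ids <- samples$sample_id[samples$phenotype == "NDD"]
    ca_ids <- samples$sample_id[samples$phenotype == "CA"]
    ctrl_ids <- samples$sample_id[samples$phenotype == "control"]

    ## Background noise never hits planted case genes: those are by
    ## definition rare in every cohort but the one they are planted in,
    ## and at desk scale a single stray carrier would contradict the
    ## planted category (1/400 already exceeds the 0.001 control filter).
    planted_case_genes <- c(shared_del, shared_dup, private_ndd,
                            private_ca)
    noise_pool <- setdiff(syms, planted_case_genes)
    noise_cnvs <- function(cohort_ids, phenotype) {
      carriers <- cohort_ids[stats::runif(length(cohort_ids)) <= noise_rate]
      if (!length(carriers)) return(NULL)
      g <- sample(noise_pool, length(carriers), replace = TRUE)
      spans <- gene_span(genome, unique(g))
      do.call(rbind, lapply(seq_along(carriers), function(i) {
        plant_cnv(spans[spans$symbol == g[i], ], carriers[i],
                  sex_of[[carriers[i]]],
                  sample(c("deletion", "duplication"), 1),
                  sample(c("VUS", "likely_benign", "benign", "pathogenic"),
                         1, prob = c(0.5, 0.15, 0.25, 0.1)),
                  sample(c("familial", "unknown", "de_novo"), 1,
                         prob = c(0.7, 0.2, 0.1)),
                  phenotype)
      }))
    }
    control_cnvs <- function() {
      spans <- gene_span(genome, control_common)
      rows <- lapply(seq_along(control_common), function(i) {
        carriers <- ctrl_ids[stats::runif(length(ctrl_ids)) <=
                               control_recurrence]
        if (!length(carriers)) return(NULL)
        do.call(rbind, lapply(carriers, function(sid)
          plant_cnv(spans[i, ], sid, sex_of[[sid]],
                    sample(c("deletion", "duplication"), 1), "benign",
                    "unknown", "control")))
      })
      do.call(rbind, c(rows, list(noise_cnvs(ctrl_ids, "control"))))
    }

    finish <- function(df) {
      if (is.null(df))
        df <- data.frame(sample_id = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         cnv_type = character(),
                         pathogenicity = character(),
                         inheritance = character(), sex = character(),
                         phenotype = character(), size = numeric())
      df <- df[order(chrom_order(df$chrom), df$start), , drop = FALSE]
      rownames(df) <- NULL
      df
    }
    ndd <- finish(rbind(
      plant_set(shared_del, ndd_ids, "deletion", "NDD"),
      plant_set(shared_dup, ndd_ids, "duplication", "NDD"),
      plant_set(private_ndd, ndd_ids, "deletion", "NDD"),
      noise_cnvs(ndd_ids, "NDD")))
    ca <- finish(rbind(
      plant_set(shared_del, ca_ids, "deletion", "CA"),
      plant_set(shared_dup, ca_ids, "duplication", "CA"),
      plant_set(private_ca, ca_ids, "deletion", "CA"),
      noise_cnvs(ca_ids, "CA")))
    control <- finish(control_cnvs())

    truth <- structure(list(
      planted_shared_genes = c(shared_del, shared_dup),
      shared_deletion_genes = shared_del,
      shared_duplication_genes = shared_dup,
      planted_private_genes = list(NDD = private_ndd, CA = private_ca),
      planted_control_common_genes = control_common,
      planted_constraint_genes = c(shared_del, shared_dup),
      planted_enriched_pathways = character(),
      seed = seed), class = "ground_truth")
    list(ndd = ndd, ca = ca, control = control, samples = samples,
         truth = truth)
  })
}

#' Generate synthetic brain expression, mutation burden and pLI
#'
#' RPKM values are log-normal. Exons of planted constraint genes receive a
#' log-mean shift of `effect_size` standard deviations in every sample,
#' plus a prenatal boost (and a smaller adult boost) so prenatal > adult >
#' early-childhood mean ordering holds for constraint genes. Burden is
#' Poisson: low rate for constraint exons, higher for background. pLI is
#' at least 0.9 for constraint genes and below 0.9 otherwise, with
#' optional label noise. Deterministic under `seed`.
#'
#' @param genome a `gene_models` object.
#' @param truth a `ground_truth` (supplies constraint genes).
#' @param n_per_stage samples per developmental stage (at least 3).
#' @param effect_size constraint-exon shift in units of `sdlog`.
#' @param prenatal_boost extra prenatal log-mean shift for constraint
#'   exons; adults receive 40% of it.
#' @param base_meanlog,sdlog background log-normal parameters.
#' @param burden_lambda_bg,burden_lambda_constraint Poisson burden rates.
#' @param pli_label_noise fraction of genes whose pLI label is flipped.
#' @param seed RNG seed.
#' @return List with `expr` (an `exon_expression`), `burden` (named
#'   vector) and `pli` (named vector).
#' @export
generate_expression_and_burden <- function(genome, truth,
                                           n_per_stage = 20,
                                           effect_size = 2,
                                           prenatal_boost = 0.75,
                                           base_meanlog = 1, sdlog = 1,
                                           burden_lambda_bg = 8,
                                           burden_lambda_constraint = 1,
                                           pli_label_noise = 0,
                                           seed = 1) {
  if (n_per_stage < 3)
    stop("need at least 3 samples per stage", call. = FALSE)
  with_seed(seed, {
    exon_ids <- genome$cds$cds_id
    is_constraint <- genome$cds$symbol %in% truth$planted_constraint_genes
    n <- 3 * n_per_stage
    stage <- rep(c("prenatal", "early_childhood", "adult"),
                 each = n_per_stage)
    meta <- data.frame(
      sample_id = sprintf("BR%03d", seq_len(n)),
      donor_id = sprintf("D%03d", ceiling(seq_len(n) / 2)),
      brain_region = rep_len(.brain_regions, n),
      stage = stage)
    meanlog <- matrix(base_meanlog, nrow = length(exon_ids), ncol = n)
    meanlog[is_constraint, ] <- meanlog[is_constraint, ] +
      effect_size * sdlog
    meanlog[is_constraint, stage == "prenatal"] <-
      meanlog[is_constraint, stage == "prenatal"] + prenatal_boost
    meanlog[is_constraint, stage == "adult"] <-
      meanlog[is_constraint, stage == "adult"] + 0.4 * prenatal_boost
    vals <- matrix(stats::rlnorm(length(meanlog), meanlog, sdlog),
                   nrow = length(exon_ids),
                   dimnames = list(exon_ids, meta$sample_id))
    expr <- exon_expression(vals, meta)
    burden <- stats::setNames(
      stats::rpois(length(exon_ids),
                   ifelse(is_constraint, burden_lambda_constraint,
                          burden_lambda_bg)),
      exon_ids)
    syms <- genome$genes$symbol
    con_gene <- syms %in% truth$planted_constraint_genes
    if (pli_label_noise > 0) {
      flip <- stats::runif(length(syms)) < pli_label_noise
      con_gene <- xor(con_gene, flip)
    }
    pli <- stats::setNames(
      ifelse(con_gene, stats::runif(length(syms), 0.9, 1),
             stats::runif(length(syms), 0, 0.89)), syms)
    list(expr = expr, burden = burden, pli = pli)
  })
}

#' Generate a synthetic GMT collection with one planted pathway
#'
#' The first pathway contains every planted constraint gene, filled with
#' random genes to `planted_size`; the remainder are uniform random sets.
#' Deterministic under `seed`.
#'
#' @param genome a `gene_models` object.
#' @param truth a `ground_truth`.
#' @param n_pathways total pathways (including the planted one).
#' @param size_range null-pathway size range, within the testable (50,
#'   1000) bounds.
#' @param planted_size size of the planted pathway.
#' @param seed RNG seed.
#' @return A `gene_set_collection`; the planted pathway id is attached as
#'   the `"planted_id"` attribute.
#' @export
generate_gmt <- function(genome, truth, n_pathways = 100,
                         size_range = c(60, 200), planted_size = 100,
                         seed = 1) {
  syms <- genome$genes$symbol
  if (max(size_range, planted_size) > length(syms))
    stop("requested pathway size exceeds the gene count", call. = FALSE)
  with_seed(seed, {
    planted <- truth$planted_constraint_genes
    fill <- sample(setdiff(syms, planted),
                   max(0, planted_size - length(planted)))
    sets <- vector("list", n_pathways)
    sets[[1]] <- list(name = "planted developmental pathway",
                      genes = sort(c(planted, fill)))
    for (i in seq_len(n_pathways - 1) + 1) {
      sz <- sample(seq(size_range[1], size_range[2]), 1)
      sets[[i]] <- list(name = sprintf("random pathway %d", i),
                        genes = sort(sample(syms, sz)))
    }
    names(sets) <- sprintf("PATH%04d", seq_len(n_pathways))
    structure(sets, class = "gene_set_collection",
              planted_id = "PATH0001")
  })
}

#' Generate synthetic multi-tissue proteome and exon-array tables
#'
#' Spectral counts are Poisson with a planted high-expression tissue for
#' constraint genes; log2 exon-array intensities are normal around the
#' expression-call threshold. Deterministic under `seed`.
#'
#' @param genome a `gene_models` object.
#' @param truth a `ground_truth`.
#' @param tissues tissue labels.
#' @param high_tissue tissue planted high for constraint genes.
#' @param seed RNG seed.
#' @return List with `spectral_counts` and `log2_intensity` gene x tissue
#'   matrices.
#' @export
generate_tissue_tables <- function(genome, truth,
                                   tissues = c("brain", "heart", "liver",
                                               "kidney", "lung", "testis",
                                               "ovary", "pancreas"),
                                   high_tissue = "testis", seed = 1) {
  with_seed(seed, {
    syms <- genome$genes$symbol
    lam <- matrix(5, nrow = length(syms), ncol = length(tissues),
                  dimnames = list(syms, tissues))
    lam[syms %in% truth$planted_constraint_genes, high_tissue] <- 30
    sc <- matrix(stats::rpois(length(lam), lam), nrow = length(syms),
                 dimnames = dimnames(lam))
    li <- matrix(stats::rnorm(length(lam), 6.5, 1.5), nrow = length(syms),
                 dimnames = dimnames(lam))
    list(spectral_counts = sc, log2_intensity = li)
  })
}

#' Write ground truth as JSON
#'
#' @param truth a `ground_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read ground truth JSON
#'
#' @param path JSON path written by [write_ground_truth()].
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_private_genes <- lapply(x$planted_private_genes, as.character)
  structure(x, class = "ground_truth")
}

#' Simulate a complete study on disk
#'
#' Generates the desk-scale preset (300 NDD + 150 CA + 400 control
#' samples, 500 genes, 60 brain expression samples) and writes every
#' pipeline input to `out_dir`: CNV tables, sample table, GTF annotation,
#' expression matrix and metadata, burden and pLI tables, GMT collection,
#' tissue tables and `ground_truth.json`.
#'
#' @param out_dir output directory.
#' @param seed master seed; all component seeds derive from it.
#' @param n_genes,n_ndd,n_ca,n_controls preset scale overrides.
#' @param ... further arguments passed to [generate_cohorts()].
#' @return Named list of written paths plus `truth`, invisibly.
#' @export
simulate_study <- function(out_dir, seed = 1, n_genes = 500, n_ndd = 300,
                           n_ca = 150, n_controls = 400, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed) %% 2147480000L
  genome <- generate_genome(n_genes = n_genes, seed = seed)
  coh <- generate_cohorts(genome, n_ndd = n_ndd, n_ca = n_ca,
                          n_controls = n_controls, seed = seed + 1L, ...)
  eb <- generate_expression_and_burden(genome, coh$truth, seed = seed + 2L)
  gmt <- generate_gmt(genome, coh$truth, seed = seed + 3L)
  coh$truth$planted_enriched_pathways <- attr(gmt, "planted_id")
  tt <- generate_tissue_tables(genome, coh$truth, seed = seed + 4L)

  p <- function(f) file.path(out_dir, f)
  write_cnv_table(coh$ndd, p("ndd_cnvs.tsv"))
  write_cnv_table(coh$ca, p("ca_cnvs.tsv"))
  write_cnv_table(coh$control, p("control_cnvs.tsv"))
  utils::write.table(coh$samples, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  export_gtf(genome, p("genome.gtf"))
  write_expression_matrix(eb$expr, p("expression.tsv"),
                          p("expression_meta.tsv"))
  utils::write.table(data.frame(exon_id = names(eb$burden),
                                burden = unname(eb$burden)),
                     p("burden.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(symbol = names(eb$pli),
                                pli = unname(eb$pli)),
                     p("pli.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(gmt, p("pathways.gmt"))
  utils::write.table(data.frame(symbol = rownames(tt$spectral_counts),
                                tt$spectral_counts, check.names = FALSE),
                     p("proteome.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_ground_truth(coh$truth, p("ground_truth.json"))
  ccv_log("synthetic_cohort", "simulated study written to ", out_dir)
  invisible(list(
    dir = out_dir,
    ndd_cnvs = p("ndd_cnvs.tsv"), ca_cnvs = p("ca_cnvs.tsv"),
    control_cnvs = p("control_cnvs.tsv"), samples = p("samples.tsv"),
    gene_models = p("genome.gtf"), expression = p("expression.tsv"),
    expression_meta = p("expression_meta.tsv"), burden = p("burden.tsv"),
    pli = p("pli.tsv"), gmt = p("pathways.gmt"),
    proteome = p("proteome.tsv"),
    ground_truth = p("ground_truth.json"),
    truth = coh$truth, n_controls = n_controls))
}

#' Export a gene-model annotation as GTF
#'
#' One `CDS` feature line per interval, carrying `gene_id` and
#' `gene_name` attributes; [read_gene_models()] reads it back.
#'
#' @param models a `gene_models` object.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
export_gtf <- function(models, path) {
  cds <- models$cds
  lines <- sprintf(
    "%s\tsynthetic\tCDS\t%d\t%d\t.\t%s\t0\tgene_id \"%s\"; gene_name \"%s\";",
    cds$chrom, cds$start, cds$end, cds$strand, cds$gene_id, cds$symbol)
  writeLines(lines, path)
  invisible(path)
}
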