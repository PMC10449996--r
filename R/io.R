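## Readers, writers and domain-type constructors shared by all stages.
## Internal coordinates are 1-based inclusive everywhere; BED input is
## converted at the boundary.

# ---- logging ---------------------------------------------------------------

#' @noRd
ccv_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# ---- enum vocabulary -------------------------------------------------------

.cnv_enums <- list(
  cnv_type = c(deletion = "deletion", del = "deletion", loss = "deletion",
               duplication = "duplication", dup = "duplication",
               gain = "duplication"),
  pathogenicity = c(pathogenic = "pathogenic",
                    likely_pathogenic = "likely_pathogenic",
                    "likely pathogenic" = "likely_pathogenic",
                    vus = "VUS", "uncertain" = "VUS",
                    likely_benign = "likely_benign",
                    "likely benign" = "likely_benign",
                    benign = "benign"),
  inheritance = c(de_novo = "de_novo", denovo = "de_novo",
                  "de novo" = "de_novo", familial = "familial",
                  inherited = "familial", unknown = "unknown"),
  sex = c(male = "male", m = "male", female = "female", f = "female"),
  phenotype = c(ndd = "NDD", ca = "CA", control = "control")
)

.valid_chroms <- c(as.character(1:22), "X", "Y")

## Case-insensitive enum normalisation with documented clinical synonyms
## ("loss" -> deletion, "gain" -> duplication, "denovo" -> de_novo, ...).
#' @noRd
normalize_enum <- function(x, field) {
  map <- .cnv_enums[[field]]
  key <- tolower(trimws(as.character(x)))
  out <- unname(map[key])
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(sprintf("unknown %s token(s): %s", field,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  out
}

#' @noRd
normalize_chrom <- function(x) {
  x <- sub("^chr", "", trimws(as.character(x)), ignore.case = TRUE)
  x <- toupper(x)
  bad <- setdiff(unique(x), .valid_chroms)
  if (length(bad))
    stop("chromosome(s) outside the declared contig set (1-22, X, Y): ",
         paste(bad, collapse = ", "), call. = FALSE)
  x
}

#' @noRd
chrom_order <- function(x) match(x, .valid_chroms)

# ---- CNV call tables -------------------------------------------------------

#' Read a CNV call table
#'
#' Parses a tab-separated table of CNV calls, one row per call per sample.
#' A header must name at least `sample`, `chrom`, `start`, `end`, `type`,
#' `pathogenicity`, `inheritance`, `sex` and `phenotype` (the latter may be
#' supplied via `phenotype_default` instead). Enum tokens are matched
#' case-insensitively with clinical synonyms (`loss`/`gain`,
#' `denovo`, `m`/`f`). Coordinates are 1-based inclusive.
#'
#' @param path path to the TSV file.
#' @param phenotype_default optional phenotype (`"NDD"`, `"CA"`,
#'   `"control"`) used when the file lacks a phenotype column.
#' @return A data frame of CNV calls sorted by (chrom, start) with columns
#'   `sample_id`, `chrom`, `start`, `end`, `cnv_type`, `pathogenicity`,
#'   `inheritance`, `sex`, `phenotype` and derived `size` (bp,
#'   end - start + 1).
#' @export
read_cnv_table <- function(path, phenotype_default = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  names(raw) <- tolower(names(raw))
  required <- c("sample", "chrom", "start", "end", "type", "pathogenicity",
                "inheritance", "sex")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("CNV table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"phenotype" %in% names(raw)) {
    if (is.null(phenotype_default))
      stop("CNV table is missing required column(s): phenotype",
           call. = FALSE)
    raw$phenotype <- phenotype_default
  }
  extras <- setdiff(names(raw), c(required, "phenotype"))
  if (length(extras)) {
    warning("ignoring unrecognized column(s): ",
            paste(extras, collapse = ", "), call. = FALSE)
    ccv_log("io", "ignored extra CNV-table columns: ",
            paste(extras, collapse = ", "))
  }
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  bad_num <- which(is.na(start) | is.na(end))
  if (length(bad_num))
    stop("non-numeric start/end at line ", bad_num[1] + 1L, call. = FALSE)
  bad <- which(end < start | start < 1)
  if (length(bad))
    stop("invalid interval (end < start or start < 1) at line ",
         bad[1] + 1L, " of ", path, call. = FALSE)
  calls <- data.frame(
    sample_id = raw$sample,
    chrom = normalize_chrom(raw$chrom),
    start = start,
    end = end,
    cnv_type = normalize_enum(raw$type, "cnv_type"),
    pathogenicity = normalize_enum(raw$pathogenicity, "pathogenicity"),
    inheritance = normalize_enum(raw$inheritance, "inheritance"),
    sex = normalize_enum(raw$sex, "sex"),
    phenotype = normalize_enum(raw$phenotype, "phenotype"),
    stringsAsFactors = FALSE
  )
  calls$size <- calls$end - calls$start + 1
  calls <- calls[order(chrom_order(calls$chrom), calls$start), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Write a CNV call table
#'
#' Inverse of [read_cnv_table()]; writing then reading reproduces content.
#'
#' @param calls CNV call data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cnv_table <- function(calls, path) {
  out <- data.frame(sample = calls$sample_id, chrom = calls$chrom,
                    start = calls$start, end = calls$end,
                    type = calls$cnv_type,
                    pathogenicity = calls$pathogenicity,
                    inheritance = calls$inheritance, sex = calls$sex,
                    phenotype = calls$phenotype)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- gene models -----------------------------------------------------------

#' Construct a gene-model annotation
#'
#' Duplicate CDS intervals (identical gene, chrom, start and end) are
#' collapsed to a single interval; each retained interval receives a unique
#' CDS id. Genes whose input rows disagree on strand are rejected.
#'
#' @param cds data frame with columns `gene_id`, `symbol`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive), one row per CDS
#'   interval.
#' @param pli optional named numeric vector of pLI scores keyed by symbol.
#' @param omim_genes optional character vector of symbols with an OMIM
#'   entry.
#' @return An object of class `gene_models`: a list with `genes` (one row
#'   per gene: `gene_id`, `symbol`, `chrom`, `strand`, `is_omim`, `pli`)
#'   and `cds` (one row per deduplicated CDS interval, with `cds_id`).
#' @export
gene_models <- function(cds, pli = NULL, omim_genes = NULL) {
  need <- c("gene_id", "symbol", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(cds))
  if (length(miss))
    stop("cds table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(cds) == 0)
    stop("annotation contains no CDS features", call. = FALSE)
  if (any(cds$end < cds$start))
    stop("degenerate CDS interval (end < start)", call. = FALSE)
  cds$start <- as.integer(cds$start)  # integer coordinates keep cds_ids
  cds$end <- as.integer(cds$end)      # free of scientific notation
  cds$chrom <- normalize_chrom(cds$chrom)
  strands <- tapply(cds$strand, cds$gene_id, function(s) length(unique(s)))
  if (any(strands > 1))
    stop("mixed-strand annotation for gene(s): ",
         paste(names(strands)[strands > 1], collapse = ", "),
         call. = FALSE)
  key <- paste(cds$gene_id, cds$chrom, cds$start, cds$end, sep = "\r")
  cds <- cds[!duplicated(key), , drop = FALSE]
  cds <- cds[order(chrom_order(cds$chrom), cds$start, cds$gene_id), ,
             drop = FALSE]
  cds$cds_id <- paste(cds$gene_id, cds$chrom, cds$start, cds$end, sep = ":")
  rownames(cds) <- NULL
  genes <- cds[!duplicated(cds$gene_id),
               c("gene_id", "symbol", "chrom", "strand")]
  rownames(genes) <- NULL
  genes$is_omim <- if (is.null(omim_genes)) FALSE else
    genes$symbol %in% omim_genes
  genes$pli <- if (is.null(pli)) NA_real_ else
    unname(pli[genes$symbol])
  if (any(!is.na(genes$pli) & (genes$pli < 0 | genes$pli > 1)))
    stop("pLI values must lie in [0, 1]", call. = FALSE)
  structure(list(genes = genes,
                 cds = cds[, c("cds_id", "gene_id", "symbol", "chrom",
                               "strand", "start", "end")]),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d CDS intervals on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$cds), length(unique(x$cds$chrom))))
  invisible(x)
}

#' Read gene models from GTF or BED12
#'
#' GTF `CDS` features are grouped by `gene_id`; BED12 blocks are treated as
#' CDS intervals and converted from 0-based half-open to 1-based inclusive
#' coordinates. Duplicate intervals are collapsed (see [gene_models()]).
#'
#' @param path annotation file path.
#' @param dialect `"gtf"` or `"bed12"`.
#' @param pli,omim_genes passed to [gene_models()].
#' @param contig_lengths optional named vector of contig lengths; intervals
#'   extending past a declared length are rejected.
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(path, dialect = c("gtf", "bed12"),
                             pli = NULL, omim_genes = NULL,
                             contig_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
    if (length(gr) == 0)
      stop("annotation contains no CDS features", call. = FALSE)
    sym <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
    sym[is.na(sym)] <- gr$gene_id[is.na(sym)]
    cds <- data.frame(
      gene_id = gr$gene_id,
      symbol = sym,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0)
      stop("annotation contains no CDS features", call. = FALSE)
    if (!is.null(gr$blocks)) {
      bl <- rtracklayer::blocks(gr)  # absolute, 1-based inclusive
      n_per <- S4Vectors::elementNROWS(bl)
      flat <- unlist(bl, use.names = FALSE)
      cds <- data.frame(
        gene_id = rep(gr$name, n_per),
        symbol = rep(gr$name, n_per),
        chrom = as.character(GenomicRanges::seqnames(flat)),
        strand = rep(as.character(GenomicRanges::strand(gr)), n_per),
        start = GenomicRanges::start(flat),
        end = GenomicRanges::end(flat),
        stringsAsFactors = FALSE
      )
    } else {
      cds <- data.frame(
        gene_id = gr$name, symbol = gr$name,
        chrom = as.character(GenomicRanges::seqnames(gr)),
        strand = as.character(GenomicRanges::strand(gr)),
        start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr),
        stringsAsFactors = FALSE
      )
    }
  }
  cds$strand[!cds$strand %in% c("+", "-")] <- "+"
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[normalize_chrom(cds$chrom)]
    over <- which(!is.na(lim) & cds$end > lim)
    if (length(over))
      stop("CDS interval(s) extend past the declared contig length for: ",
           paste(unique(cds$gene_id[over]), collapse = ", "), call. = FALSE)
  }
  gene_models(cds, pli = pli, omim_genes = omim_genes)
}

#' Map exon/CDS ids to gene symbols
#'
#' @param models a `gene_models` object.
#' @return Named character vector: `cds_id` -> gene symbol.
#' @export
exon_to_gene_map <- function(models) {
  stats::setNames(models$cds$symbol, models$cds$cds_id)
}

# ---- gene sets (GMT) -------------------------------------------------------

#' Read a GMT gene-set collection
#'
#' Standard GMT: one tab-separated record per line, `id`, `description`,
#' then member gene symbols. Duplicate ids are an error; an empty file
#' yields an empty collection with a warning.
#'
#' @param path GMT file path.
#' @return Object of class `gene_set_collection`: a named list of
#'   `list(name =, genes =)` entries keyed by pathway id.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(structure(list(), class = "gene_set_collection"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate pathway id(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  sets <- lapply(parts, function(p)
    list(name = p[[2L]], genes = unique(p[-(1:2)][nzchar(p[-(1:2)])])))
  names(sets) <- ids
  structure(sets, class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(id) {
    s <- collection[[id]]
    paste(c(id, s$name, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# ---- expression matrices and per-exon vectors ------------------------------

#' Read an exon-by-sample expression matrix with sample metadata
#'
#' The matrix TSV has exon ids in the first column and sample ids as the
#' header; the metadata TSV carries `sample_id`, `donor_id`,
#' `brain_region` and `stage` (`prenatal`, `early_childhood`, `adult`).
#'
#' @param path matrix TSV path.
#' @param meta_path sample metadata TSV path.
#' @return Object of class `exon_expression`: `list(values = matrix,
#'   meta = data.frame)`.
#' @export
read_expression_matrix <- function(path, meta_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  exon_ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) | anyNA(vals)) {
    at <- if (nrow(bad)) bad[1, ] else which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing cell at exon '%s', sample '%s'",
                 exon_ids[at[1]], colnames(vals)[at[2]]), call. = FALSE)
  }
  dimnames(num) <- list(exon_ids, colnames(vals))
  if (any(num < 0))
    stop("expression values must be non-negative", call. = FALSE)
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            colClasses = "character")
  need <- c("sample_id", "donor_id", "brain_region", "stage")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sample metadata missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  exon_expression(num, meta)
}

#' Construct an exon-expression object
#'
#' @param values non-negative numeric matrix, exons in rows, samples in
#'   columns, both dimnames set.
#' @param meta data frame with one row per sample (`sample_id`,
#'   `donor_id`, `brain_region`, `stage`).
#' @return An `exon_expression` object.
#' @export
exon_expression <- function(values, meta) {
  stages <- c("prenatal", "early_childhood", "adult")
  meta$stage <- tolower(meta$stage)
  if (!all(meta$stage %in% stages))
    stop("unknown developmental stage label(s): ",
         paste(setdiff(unique(meta$stage), stages), collapse = ", "),
         call. = FALSE)
  if (!setequal(colnames(values), meta$sample_id))
    stop("matrix columns and sample metadata disagree", call. = FALSE)
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "exon_expression")
}

#' @export
print.exon_expression <- function(x, ...) {
  cat(sprintf("exon_expression: %d exons x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$meta$stage)),
                            table(x$meta$stage)), collapse = ", ")))
  invisible(x)
}

#' Write an exon-expression matrix and its sample metadata
#'
#' @param expr an `exon_expression` object.
#' @param path,meta_path output TSV paths.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, meta_path) {
  df <- data.frame(exon_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-exon rare non-synonymous mutation-burden vector
#'
#' @param path TSV with columns `exon_id` and `burden` (non-negative
#'   counts of rare, frequency < 0.01, non-synonymous variants).
#' @return Named numeric vector keyed by exon id.
#' @export
read_exon_burden <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("exon_id", "burden") %in% names(df)))
    stop("burden table must have columns exon_id and burden", call. = FALSE)
  b <- as.numeric(df$burden)
  if (anyNA(b) || any(b < 0))
    stop("burdens must be non-negative numbers", call. = FALSE)
  stats::setNames(b, df$exon_id)
}

#' Read per-gene pLI scores
#'
#' @param path TSV with columns `symbol` and `pli` (probability in
#'   \[0, 1\]).
#' @return Named numeric vector keyed by gene symbol.
#' @export
read_pli <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("symbol", "pli") %in% names(df)))
    stop("pLI table must have columns symbol and pli", call. = FALSE)
  p <- as.numeric(df$pli)
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("pLI values must lie in [0, 1]", call. = FALSE)
  stats::setNames(p, df$symbol)
}

# ---- result output ---------------------------------------------------------

#' Write result tables as TSV files
#'
#' Each element of `tables` (a data frame) is written to
#' `<out_dir>/<name>.tsv` with a header; writing then re-reading
#' reproduces content.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, "")
  ccv_log("io", "wrote ", length(paths), " result table(s) to ", out_dir)
  invisible(paths)
}
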