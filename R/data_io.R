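#' Read a gene annotation from BED or GFF3
#'
#' BED input is BED6 plus two extra columns (`neoY_orf`,
#' `n_informative_snps`); GFF3 input carries the same information in the
#' attribute column (`ID` or `gene_id`, plus optional `neoY_orf` and
#' `n_informative_snps` attributes). Coordinates are stored 0-based
#' half-open (BED convention); GFF3 1-based coordinates are converted on
#' read.
#'
#' @param path file path.
#' @param format `"bed"` or `"gff"`.
#' @return a [gene_annotation] data.frame.
#' @export
read_annotation <- function(path, format = c("bed", "gff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "bed") {
    gr <- tryCatch(
      rtracklayer::import(path, format = "BED",
                          extraCols = c(neoY_orf = "character",
                                        n_informative_snps = "integer")),
      error = function(e) stop("BED parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    df <- data.frame(
      gene_id = gr$name,
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # GRanges is 1-based closed
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      neoY_orf = gr$neoY_orf,
      n_informative_snps = gr$n_informative_snps,
      stringsAsFactors = FALSE)
    df$strand[df$strand == "*"] <- "."
  } else {
    gr <- tryCatch(
      rtracklayer::import(path, format = "GFF3"),
      error = function(e) stop("GFF parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    meta <- S4Vectors::mcols(gr)
    ids <- if (!is.null(meta$ID)) as.character(meta$ID) else as.character(meta$gene_id)
    if (is.null(ids) || anyNA(ids)) stop("GFF records lack ID/gene_id attributes")
    orf <- if (!is.null(meta$neoY_orf)) as.character(meta$neoY_orf) else "not_applicable"
    nsnp <- if (!is.null(meta$n_informative_snps)) {
      as.integer(as.character(meta$n_informative_snps))
    } else 0L
    df <- data.frame(
      gene_id = ids,
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      neoY_orf = orf,
      n_informative_snps = nsnp,
      stringsAsFactors = FALSE)
    df$strand[df$strand == "*"] <- "."
    df$neoY_orf[is.na(df$neoY_orf)] <- "not_applicable"
    df$n_informative_snps[is.na(df$n_informative_snps)] <- 0L
  }
  gene_annotation(df)
}

#' Write a gene annotation as BED6+2
#'
#' Inverse of [read_annotation()] for the BED dialect; round-trips exactly.
#'
#' @param ann a [gene_annotation].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  out <- data.frame(ann$chromosome, ann$start, ann$end, ann$gene_id,
                    0L, ann$strand, ann$neoY_orf, ann$n_informative_snps)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read an expression table from TSV
#'
#' First column `gene_id`, remaining columns one per sample, values RPKM.
#'
#' @param path TSV file path.
#' @return an [expression_table].
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path, "expression")
  if (names(df)[1] != "gene_id") stop("first expression column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene_id
  if (anyNA(m)) stop("missing values in expression table")
  if (any(m < 0)) stop("negative values in expression table")
  expression_table(m)
}

#' Write an expression table to TSV
#' @param expr an [expression_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_table"))
  df <- data.frame(gene_id = rownames(expr$values),
                   signif(expr$values, 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-count table from TSV
#' @param path TSV with columns gene_id, sample_id, maternal_reads,
#'   paternal_reads, n_snps_observed and optionally neoX_reads, neoY_reads.
#' @return an [allele_counts] data.frame.
#' @export
read_allele_counts <- function(path) {
  allele_counts(read_tsv_checked(path, "allele-count"))
}

#' Write an allele-count table to TSV
#' @param allele an [allele_counts] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(allele, path) {
  stopifnot(inherits(allele, "allele_counts"))
  out <- as.data.frame(allele)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#' @param path TSV with columns sample_id, species, stage, sex, replicate.
#' @return a [sample_sheet].
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(read_tsv_checked(path, "sample sheet"))
}

#' Write a sample sheet to TSV
#' @param sheet a [sample_sheet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(inherits(sheet, "sample_sheet"))
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and cross-validate the expression / allele / sample-sheet triple
#'
#' Samples present in the expression table must appear in the sheet; allele
#' rows must refer to known samples. Genes lacking allele rows are recorded
#' in the `no_allele_info` attribute of the result (absence of SNPs is not
#' zero counts).
#'
#' @param expr_path,allele_path,sheet_path TSV file paths.
#' @param ann optional [gene_annotation] for additional checks (male X
#'   paternal reads must be zero).
#' @return list with elements `expr`, `allele`, `sheet`.
#' @export
read_tables <- function(expr_path, allele_path, sheet_path, ann = NULL) {
  expr <- read_expression(expr_path)
  allele <- read_allele_counts(allele_path)
  sheet <- read_sample_sheet(sheet_path)
  validate_tables(expr, allele, sheet, ann)
}

#' Cross-validate already-loaded tables
#'
#' @param expr an [expression_table].
#' @param allele an [allele_counts] table.
#' @param sheet a [sample_sheet].
#' @param ann optional [gene_annotation]; when given, sex-linkage consistency
#'   is checked: male samples must have zero paternal reads on X-linked
#'   genes.
#' @return list `(expr, allele, sheet)` with attribute `no_allele_info`
#'   listing genes without any allele data.
#' @export
validate_tables <- function(expr, allele, sheet, ann = NULL) {
  stopifnot(inherits(expr, "expression_table"),
            inherits(allele, "allele_counts"),
            inherits(sheet, "sample_sheet"))
  missing_samples <- setdiff(colnames(expr$values), sheet$sample_id)
  if (length(missing_samples) > 0L) {
    stop("expression sample(s) absent from sample sheet: ",
         paste(missing_samples, collapse = ", "))
  }
  stray <- setdiff(unique(allele$sample_id), sheet$sample_id)
  if (length(stray) > 0L) {
    stop("allele-table sample(s) absent from sample sheet: ",
         paste(stray, collapse = ", "))
  }
  if (!is.null(ann)) {
    stopifnot(inherits(ann, "gene_annotation"))
    cls <- chromosome_class(ann$chromosome)[match(allele$gene_id, ann$gene_id)]
    sex <- sheet$sex[match(allele$sample_id, sheet$sample_id)]
    bad <- !is.na(cls) & cls == "X" & sex == "male" & allele$paternal_reads > 0
    if (any(bad)) {
      stop("male sample(s) with paternal X reads (males carry no paternal X): ",
           paste(utils::head(unique(allele$sample_id[bad]), 5L), collapse = ", "))
    }
  }
  res <- list(expr = expr, allele = allele, sheet = sheet)
  attr(res, "no_allele_info") <-
    setdiff(rownames(expr$values), unique(allele$gene_id))
  res
}

#' Verify embryo sex from allele-specific X-chromosome data
#'
#' Males carry a single, maternally inherited X, so the paternal read
#' fraction over X-linked genes is ~0 in males and near the biallelic
#' expectation (~0.5 of zygotic reads) in females. Samples without zygotic
#' transcription (pre-MZT stages) carry no paternal signal in either sex on
#' any chromosome and are called `unknown`; we require a detectable
#' autosomal paternal fraction before attempting a call. Disagreements with
#' the sheet are reported, never overwritten.
#'
#' @param expr an [expression_table] (currently unused beyond the interface;
#'   calls rest on the allele data).
#' @param allele an [allele_counts] table.
#' @param ann a [gene_annotation].
#' @param sheet a [sample_sheet].
#' @param male_max_paternal X paternal fraction at or below which a sample is
#'   called male (default 0.02).
#' @param female_band numeric length-2; X paternal fraction band called
#'   female (default `c(0.3, 0.7)`); note the X paternal fraction is of
#'   total (maternal + zygotic) reads, so values well below 0.5 still
#'   indicate a female.
#' @param min_autosomal_paternal minimum autosomal paternal fraction required
#'   as evidence of zygotic transcription (default 0.05).
#' @param min_reads minimum total X-linked allele reads for a call.
#' @return data.frame per sample: `sample_id`, `x_paternal_fraction`,
#'   `autosomal_paternal_fraction`, `sex_call`, `sheet_sex`, `agree`.
#' @export
verify_sex <- function(expr, allele, ann, sheet,
                       male_max_paternal = 0.02,
                       female_band = c(0.3, 0.7),
                       min_autosomal_paternal = 0.05,
                       min_reads = 50) {
  stopifnot(inherits(allele, "allele_counts"), inherits(ann, "gene_annotation"),
            inherits(sheet, "sample_sheet"))
  cls <- chromosome_class(ann$chromosome)[match(allele$gene_id, ann$gene_id)]
  res <- do.call(rbind, lapply(sheet$sample_id, function(s) {
    rows <- allele$sample_id == s
    x <- rows & !is.na(cls) & cls == "X"
    a <- rows & !is.na(cls) & cls == "autosome"
    xt <- sum(allele$maternal_reads[x] + allele$paternal_reads[x])
    xp <- if (xt > 0) sum(allele$paternal_reads[x]) / xt else NA_real_
    at <- sum(allele$maternal_reads[a] + allele$paternal_reads[a])
    ap <- if (at > 0) sum(allele$paternal_reads[a]) / at else NA_real_
    call <- "unknown"
    if (!is.na(xp) && xt >= min_reads &&
        !is.na(ap) && ap >= min_autosomal_paternal) {
      if (xp <= male_max_paternal) call <- "male"
      else if (xp >= female_band[1] && xp <= female_band[2]) call <- "female"
    }
    data.frame(sample_id = s, x_paternal_fraction = xp,
               autosomal_paternal_fraction = ap,
               sex_call = call, stringsAsFactors = FALSE)
  }))
  if (all(is.na(res$x_paternal_fraction))) {
    warning("no informative X-linked allele data; all sex calls unknown")
  }
  res$sheet_sex <- sheet$sex[match(res$sample_id, sheet$sample_id)]
  res$agree <- res$sex_call == "unknown" | res$sex_call == res$sheet_sex
  n_dis <- sum(!res$agree)
  if (n_dis > 0L) {
    warning(n_dis, " sample(s) disagree between sheet sex and expression-based call")
  }
  res
}
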