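## Chromosome universe. Chr3_neoXY is the chromosome that is autosomal in the
## older karyotype (pse_like) and a neo-X/neo-Y pair in the younger one
## (mir_like).
CHROMOSOMES <- c("Chr2", "Chr4", "XL", "XR", "Chr3_neoXY")

## Ordinal developmental stages 1..8 and their morphological display labels.
STAGE_LABELS <- c("2", "4", "mid-5", "late-5", "7", "8/9", "10", "12")
N_STAGES <- 8L

SPECIES_PROFILES <- c("pse_like", "mir_like", "mel_like")

#' Chromosome class of each chromosome
#'
#' Maps chromosome names to the analysis classes used throughout:
#' `"autosome"`, `"X"` (XL and XR), or `"neoXY"`. Whether `Chr3_neoXY`
#' counts as a neo-sex chromosome or an autosome depends on the karyotype:
#' it is sex-linked only in `mir_like`-type species.
#'
#' @param chromosome character vector of chromosome names.
#' @param neo_is_sex logical; treat `Chr3_neoXY` as a neo-sex chromosome
#'   (`TRUE`, the mir_like karyotype) or as an autosome (`FALSE`).
#' @return character vector of classes, same length as `chromosome`.
#' @export
chromosome_class <- function(chromosome, neo_is_sex = TRUE) {
  bad <- setdiff(unique(chromosome), CHROMOSOMES)
  if (length(bad) > 0L) {
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  cls <- ifelse(chromosome %in% c("XL", "XR"), "X", "autosome")
  if (neo_is_sex) cls[chromosome == "Chr3_neoXY"] <- "neoXY"
  cls
}

#' Construct and validate a gene annotation table
#'
#' A gene annotation is a `data.frame` with one row per gene and columns
#' `gene_id`, `chromosome`, `start`, `end` (0-based half-open, bp),
#' `strand` (`+`, `-` or `.`), `neoY_orf` (`intact`/`broken` for genes on the
#' neo-sex chromosome, `not_applicable` otherwise) and `n_informative_snps`
#' (number of fixed differences between parental lines overlapping the gene).
#'
#' @param df data.frame with the columns above (`strand`, `neoY_orf`,
#'   `n_informative_snps` optional; defaulted to `.`, `not_applicable`, 0).
#' @return validated `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("gene_id", "chromosome", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$strand)) df$strand <- "."
  if (is.null(df$neoY_orf)) df$neoY_orf <- "not_applicable"
  if (is.null(df$n_informative_snps)) df$n_informative_snps <- 0L
  df$gene_id <- as.character(df$gene_id)
  df$chromosome <- as.character(df$chromosome)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$strand <- as.character(df$strand)
  df$neoY_orf <- as.character(df$neoY_orf)
  df$n_informative_snps <- as.integer(df$n_informative_snps)

  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$chromosome), CHROMOSOMES)
  if (length(bad) > 0L) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  if (any(df$start < 0L)) stop("negative start coordinate")
  if (any(df$start >= df$end)) {
    stop("start must be < end for gene(s): ",
         paste(utils::head(df$gene_id[df$start >= df$end], 5L), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  if (!all(df$neoY_orf %in% c("intact", "broken", "not_applicable"))) {
    stop("neoY_orf must be intact, broken or not_applicable")
  }
  # intact/broken only meaningful on the neo-sex chromosome; not_applicable is
  # allowed anywhere (Chr3 is autosomal in the older karyotype).
  off <- df$neoY_orf != "not_applicable" & df$chromosome != "Chr3_neoXY"
  if (any(off)) stop("neoY_orf set for gene(s) not on Chr3_neoXY")
  if (any(df$n_informative_snps < 0L)) stop("negative n_informative_snps")

  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Construct and validate a sample sheet
#'
#' One row per embryo: `sample_id`, `species` (`pse_like`/`mir_like`/
#' `mel_like`), `stage` (ordinal 1..8; display labels in
#' [stage_label()]), `sex` (`female`/`male`/`unknown`), `replicate`.
#'
#' @param df data.frame with the columns above.
#' @return validated `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("sample_id", "species", "stage", "sex", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$species <- as.character(df$species)
  df$stage <- as.integer(df$stage)
  df$sex <- as.character(df$sex)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  if (!all(df$species %in% SPECIES_PROFILES)) stop("unknown species label")
  if (any(df$stage < 1L | df$stage > N_STAGES)) stop("stage must be in 1..", N_STAGES)
  if (!all(df$sex %in% c("female", "male", "unknown"))) stop("sex must be female/male/unknown")
  if (any(df$replicate < 1L)) stop("replicate must be positive")
  key <- paste(df$species, df$stage, df$sex, df$replicate)
  if (anyDuplicated(key)) stop("duplicate (species, stage, sex, replicate) combination")
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Morphological label of an ordinal stage
#' @param stage integer vector in 1..8.
#' @return character vector of morphological stage labels.
#' @export
stage_label <- function(stage) {
  stopifnot(all(stage >= 1L & stage <= N_STAGES))
  STAGE_LABELS[stage]
}

#' Construct an expression table
#'
#' Holds a gene x sample matrix of abundances (RPKM) plus normalization
#' state.
#'
#' @param values numeric matrix, rows named by gene, columns by sample.
#' @param normalized logical flag.
#' @param t_ref target autosomal total used during normalization (or `NA`).
#' @return object of class `expression_table`.
#' @export
expression_table <- function(values, normalized = FALSE, t_ref = NA_real_) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  if (any(values < 0, na.rm = TRUE)) stop("negative expression values")
  structure(list(values = values, normalized = normalized, t_ref = t_ref),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) sprintf("normalized, T_ref = %.4g", x$t_ref)
              else "unnormalized"))
  invisible(x)
}

#' Construct and validate an allele-count table
#'
#' Long-format table with one row per (gene, sample) that has SNP-overlapping
#' reads available: `gene_id`, `sample_id`, `maternal_reads`,
#' `paternal_reads`, `n_snps_observed`, and (for neo-sex-chromosome genes in
#' males with neo-divergence SNPs) `neoX_reads`, `neoY_reads` (`NA`
#' elsewhere). Genes absent from the table have no allele information,
#' which is distinct from zero counts.
#'
#' @param df data.frame with the columns above (neo columns optional).
#' @return validated `data.frame` of class `allele_counts`.
#' @export
allele_counts <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("gene_id", "sample_id", "maternal_reads", "paternal_reads", "n_snps_observed")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("allele table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$neoX_reads)) df$neoX_reads <- NA_real_
  if (is.null(df$neoY_reads)) df$neoY_reads <- NA_real_
  df$gene_id <- as.character(df$gene_id)
  df$sample_id <- as.character(df$sample_id)
  for (cc in c("maternal_reads", "paternal_reads", "neoX_reads", "neoY_reads")) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  df$n_snps_observed <- as.integer(df$n_snps_observed)
  if (any(df$maternal_reads < 0 | df$paternal_reads < 0, na.rm = TRUE)) {
    stop("negative allele read counts")
  }
  if (any(df$n_snps_observed < 0L)) stop("negative n_snps_observed")
  if (anyDuplicated(paste(df$gene_id, df$sample_id))) {
    stop("duplicate (gene_id, sample_id) rows in allele table")
  }
  rownames(df) <- NULL
  class(df) <- c("allele_counts", "data.frame")
  df
}

#' Bootstrap result container
#'
#' @param point_estimate observed statistic (the sample mean).
#' @param ci_low,ci_high empirical 2.5% and 97.5% quantiles over bootstrap
#'   resamples.
#' @param n_boot number of resamples.
#' @param seed RNG seed used, or `NA`.
#' @return object of class `bootstrap_result`.
#' @export
bootstrap_result <- function(point_estimate, ci_low, ci_high, n_boot, seed = NA_integer_) {
  structure(list(point_estimate = point_estimate, ci_low = ci_low,
                 ci_high = ci_high, n_boot = n_boot, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("mean %.5g  [%.5g, %.5g]  (%d bootstrap resamples)\n",
              x$point_estimate, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}
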