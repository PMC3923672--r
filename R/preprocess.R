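#' Normalize expression so per-sample autosomal totals are constant
#'
#' Each sample is rescaled by `s_j = T_ref / sum(RPKM of reference genes in
#' sample j)`. The default reference set is chromosomes 2 and 4, autosomal
#' in every karyotype considered; `T_ref` defaults to the across-sample mean
#' of the reference totals. Alternative modes scale to all autosomes or
#' leave the RPKM values as-is (total-read normalization is already implied
#' by the RPKM unit); all modes agree on X:autosome contrasts.
#'
#' @param expr an [expression_table].
#' @param ann a [gene_annotation] matching the expression rows.
#' @param reference_chromosomes chromosomes whose summed expression is held
#'   constant (default `c("Chr2", "Chr4")`).
#' @param t_ref target total; default mean of per-sample reference totals.
#' @param mode `"reference"` (scale to `reference_chromosomes`),
#'   `"all_autosomes"`, or `"total_reads"` (no rescaling).
#' @param neo_is_sex whether `Chr3_neoXY` counts as sex-linked when
#'   expanding `"all_autosomes"`.
#' @return normalized [expression_table]; scale factors in attribute
#'   `scale_factors`.
#' @export
normalize_autosomal <- function(expr, ann,
                                reference_chromosomes = c("Chr2", "Chr4"),
                                t_ref = NULL,
                                mode = c("reference", "all_autosomes", "total_reads"),
                                neo_is_sex = TRUE) {
  stopifnot(inherits(expr, "expression_table"), inherits(ann, "gene_annotation"))
  mode <- match.arg(mode)
  if (mode == "total_reads") {
    out <- expression_table(expr$values, normalized = TRUE, t_ref = NA_real_)
    attr(out, "scale_factors") <- stats::setNames(rep(1, ncol(expr$values)),
                                                  colnames(expr$values))
    return(out)
  }
  if (mode == "all_autosomes") {
    reference_chromosomes <-
      CHROMOSOMES[chromosome_class(CHROMOSOMES, neo_is_sex) == "autosome"]
  }
  ref_genes <- ann$gene_id[ann$chromosome %in% reference_chromosomes]
  ref_genes <- intersect(ref_genes, rownames(expr$values))
  if (length(ref_genes) == 0L) stop("no reference-chromosome genes in expression table")
  totals <- colSums(expr$values[ref_genes, , drop = FALSE])
  zero <- totals <= 0
  if (any(zero)) {
    stop("zero autosomal total in sample(s): ",
         paste(colnames(expr$values)[zero], collapse = ", "))
  }
  if (is.null(t_ref)) t_ref <- mean(totals)
  s <- t_ref / totals
  out <- expression_table(sweep(expr$values, 2, s, `*`),
                          normalized = TRUE, t_ref = t_ref)
  attr(out, "scale_factors") <- s
  out
}

#' Per-gene allele fractions from SNP-overlapping read counts
#'
#' All maternal or paternal reads for each SNP of a gene are combined and
#' divided by the number of SNPs observed for that gene, yielding per-SNP
#' mean read levels; the paternal fraction `p` is
#' `paternal / (maternal + paternal)`. Rows without observed SNPs are
#' dropped (no information, not zero), and `p` is `NA` when a gene/sample
#' has SNPs but no reads.
#'
#' @param allele an [allele_counts] table.
#' @return data.frame of class `allele_fractions`: `gene_id`, `sample_id`,
#'   `maternal_per_snp`, `paternal_per_snp`, `p`.
#' @export
allele_fractions <- function(allele) {
  stopifnot(inherits(allele, "allele_counts"))
  keep <- allele$n_snps_observed >= 1L
  af <- data.frame(
    gene_id = allele$gene_id[keep],
    sample_id = allele$sample_id[keep],
    maternal_per_snp = allele$maternal_reads[keep] / allele$n_snps_observed[keep],
    paternal_per_snp = allele$paternal_reads[keep] / allele$n_snps_observed[keep],
    stringsAsFactors = FALSE)
  tot <- allele$maternal_reads[keep] + allele$paternal_reads[keep]
  af$p <- ifelse(tot > 0, allele$paternal_reads[keep] / tot, NA_real_)
  class(af) <- c("allele_fractions", "data.frame")
  af
}

#' Zygotic transcript fraction from doubled paternal read fractions
#'
#' Maternal deposition is identical between the sexes and carries only
#' maternal alleles, while zygotic transcription of a biallelic gene is
#' split evenly between alleles, so doubling the paternal read fraction
#' estimates the zygotic share of a gene's transcript pool:
#' `z = min(2 p, 1)` (clipped, since a fraction cannot exceed 1). Only
#' female embryos are used, so that X-linked genes retain a paternal allele.
#' Per-gene `z` is computed per embryo and averaged across replicates, then
#' summarized per stage and chromosome class.
#'
#' @param fractions an `allele_fractions` data.frame.
#' @param sheet a [sample_sheet].
#' @param ann a [gene_annotation].
#' @param neo_is_sex whether `Chr3_neoXY` is a neo-sex chromosome for class
#'   summaries.
#' @return list with `per_gene` (gene, stage, mean z across female
#'   replicates, chromosome class) and `by_stage` (stage x class mean z over
#'   genes).
#' @export
zygotic_fraction <- function(fractions, sheet, ann, neo_is_sex = TRUE) {
  stopifnot(inherits(sheet, "sample_sheet"), inherits(ann, "gene_annotation"))
  females <- sheet$sample_id[sheet$sex == "female"]
  f <- fractions[fractions$sample_id %in% females & !is.na(fractions$p), ,
                 drop = FALSE]
  missing_stages <- setdiff(seq_len(N_STAGES),
                            unique(sheet$stage[sheet$sex == "female"]))
  if (length(missing_stages) > 0L) {
    warning("no female samples at stage(s) ",
            paste(missing_stages, collapse = ", "), "; omitted")
  }
  if (nrow(f) == 0L) stop("no usable female allele fractions")
  f$stage <- sheet$stage[match(f$sample_id, sheet$sample_id)]
  f$z <- pmin(2 * f$p, 1)
  per_gene <- stats::aggregate(z ~ gene_id + stage, data = f, FUN = mean)
  per_gene$class <- chromosome_class(
    ann$chromosome[match(per_gene$gene_id, ann$gene_id)], neo_is_sex)
  by_stage <- stats::aggregate(z ~ stage + class, data = per_gene, FUN = mean)
  list(per_gene = per_gene, by_stage = by_stage)
}

#' Proportion of expressed genes with SNP information, per chromosome
#'
#' A gene counts as expressed when it has at least one read anywhere in the
#' dataset; the summary is the share of expressed genes that carry
#' informative SNPs.
#'
#' @param expr an [expression_table].
#' @param allele an [allele_counts] table (genes present here count as
#'   SNP-covered, as do genes with `n_informative_snps > 0`).
#' @param ann a [gene_annotation].
#' @return data.frame per chromosome: `n_expressed`, `n_with_snps`,
#'   `proportion` (`NA` when nothing is expressed).
#' @export
snp_coverage_summary <- function(expr, allele, ann) {
  stopifnot(inherits(expr, "expression_table"), inherits(ann, "gene_annotation"))
  expressed <- rownames(expr$values)[rowSums(expr$values > 0) > 0]
  covered <- union(unique(allele$gene_id),
                   ann$gene_id[ann$n_informative_snps > 0])
  out <- do.call(rbind, lapply(unique(ann$chromosome), function(ch) {
    genes <- intersect(ann$gene_id[ann$chromosome == ch], expressed)
    n_e <- length(genes)
    n_c <- length(intersect(genes, covered))
    data.frame(chromosome = ch, n_expressed = n_e, n_with_snps = n_c,
               proportion = if (n_e > 0) n_c / n_e else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
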