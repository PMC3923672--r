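#' Gene-resampling bootstrap confidence interval for a mean
#'
#' Resamples the values (genes) with replacement `n_boot` times, takes the
#' mean of each resample, and reports the empirical 2.5% and 97.5%
#' quantiles. Deterministic given `seed`.
#'
#' @param values numeric vector (one value per gene).
#' @param n_boot number of resamples (default 1000).
#' @param seed optional RNG seed.
#' @return a [bootstrap_result].
#' @export
bootstrap_mean <- function(values, n_boot = 1000, seed = NULL) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("bootstrap_mean needs at least one value")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  means <- colMeans(matrix(values[idx], nrow = n, ncol = n_boot))
  q <- stats::quantile(means, c(0.025, 0.975), names = FALSE, type = 7)
  bootstrap_result(mean(values), q[1], q[2], n_boot,
                   if (is.null(seed)) NA_integer_ else as.integer(seed))
}

## per-gene mean maternal-allele level (per-SNP reads, normalization-scaled)
## for one set of samples
maternal_level_per_gene <- function(fractions, samples, scale_factors = NULL) {
  f <- fractions[fractions$sample_id %in% samples, , drop = FALSE]
  if (nrow(f) == 0L) return(NULL)
  s <- if (is.null(scale_factors)) rep(1, nrow(f)) else scale_factors[f$sample_id]
  f$level <- f$maternal_per_snp * s
  ag <- stats::aggregate(level ~ gene_id, data = f, FUN = mean)
  stats::setNames(ag$level, ag$gene_id)
}

#' Detect the onset of male-X hypertranscription from maternal alleles
#'
#' The maternally inherited allele is directly comparable between the sexes:
#' females transcribe one maternal X (of two Xs), males transcribe their
#' single, maternal X. Without compensation the per-gene maternal-allele
#' level is equal in males and females on every chromosome; male-X
#' upregulation raises the male maternal level above the female one on the
#' X classes only. Per stage and chromosome class, this computes the mean
#' maternal-allele level per gene in each sex with gene-resampling bootstrap
#' CIs; a cell is significant when the male mean lies above the female
#' 97.5% quantile (one-sided by construction), and the onset stage for a
#' class is the earliest significant stage. Zygotic genes should be supplied
#' under the transcript-level definition to avoid conditioning an
#' allele-specific result on an allele-specific gene selection.
#'
#' @param fractions an `allele_fractions` data.frame.
#' @param sheet a [sample_sheet].
#' @param ann a [gene_annotation].
#' @param zygotic_genes character vector of gene ids to analyse.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param scale_factors optional named per-sample normalization factors (the
#'   `scale_factors` attribute of [normalize_autosomal()]).
#' @param classes chromosome classes to report (default
#'   `c("X", "autosome", "neoXY")` as present).
#' @param neo_is_sex whether `Chr3_neoXY` is sex-linked.
#' @param low_power_min minimum zygotic genes per class (classes below it
#'   are flagged low-power) and minimum genes with reads per sex and cell
#'   for CI-exclusion significance to be assessed (default 10).
#' @return list of class `onset_report`: `table` (class, stage, per-sex
#'   means and CIs, `significant`), `onset` (named vector, earliest
#'   significant stage per class), `low_power` (classes under
#'   `low_power_min` genes).
#' @export
maternal_allele_onset <- function(fractions, sheet, ann, zygotic_genes,
                                  n_boot = 1000, seed = NULL,
                                  scale_factors = NULL,
                                  classes = c("X", "autosome", "neoXY"),
                                  neo_is_sex = TRUE,
                                  low_power_min = 10L) {
  stopifnot(inherits(sheet, "sample_sheet"), inherits(ann, "gene_annotation"))
  if (!is.null(seed)) set.seed(seed)
  cls_of <- stats::setNames(chromosome_class(ann$chromosome, neo_is_sex), ann$gene_id)
  zygotic_genes <- intersect(zygotic_genes, ann$gene_id)
  classes <- intersect(classes, unique(cls_of[zygotic_genes]))
  low_power <- character(0)
  rows <- list()
  for (cl in classes) {
    genes <- zygotic_genes[cls_of[zygotic_genes] == cl]
    if (length(genes) < low_power_min) low_power <- c(low_power, cl)
    fr <- fractions[fractions$gene_id %in% genes, , drop = FALSE]
    for (st in sort(unique(sheet$stage))) {
      fem <- sheet$sample_id[sheet$stage == st & sheet$sex == "female"]
      mal <- sheet$sample_id[sheet$stage == st & sheet$sex == "male"]
      lf <- maternal_level_per_gene(fr, fem, scale_factors)
      lm <- maternal_level_per_gene(fr, mal, scale_factors)
      if (is.null(lf) || is.null(lm)) next
      bf <- bootstrap_mean(lf, n_boot = n_boot)
      bm <- bootstrap_mean(lm, n_boot = n_boot)
      # CI exclusion is only meaningful when both sexes have enough genes
      # with reads for the resampling distribution to be non-degenerate
      powered <- length(lf) >= low_power_min && length(lm) >= low_power_min
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, stage = st, n_genes = length(genes),
        n_data_female = length(lf), n_data_male = length(lm),
        male_mean = bm$point_estimate, male_lo = bm$ci_low, male_hi = bm$ci_high,
        female_mean = bf$point_estimate, female_lo = bf$ci_low,
        female_hi = bf$ci_high,
        significant = powered && bm$point_estimate > bf$ci_high,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  onset <- vapply(classes, function(cl) {
    sig <- tab$stage[tab$class == cl & tab$significant]
    if (length(sig) == 0L) NA_integer_ else min(sig)
  }, integer(1))
  structure(list(table = tab, onset = onset, low_power = low_power),
            class = "onset_report")
}

#' Compare per-stage zygotic transcript fractions between two datasets
#'
#' For each stage, the mean doubled-paternal-fraction estimate of the
#' zygotic share is computed per group with a gene-resampling bootstrap CI;
#' a group is flagged when its mean lies outside the other group's 95% CI.
#'
#' @param per_gene_a,per_gene_b `per_gene` tables from [zygotic_fraction()]
#'   (columns `gene_id`, `stage`, `z`), optionally restricted to one
#'   chromosome class.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return data.frame per stage: group means, CIs, and
#'   `a_outside_b` / `b_outside_a` flags.
#' @export
zygotic_fraction_compare <- function(per_gene_a, per_gene_b,
                                     n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stages <- sort(intersect(unique(per_gene_a$stage), unique(per_gene_b$stage)))
  out <- do.call(rbind, lapply(stages, function(st) {
    za <- per_gene_a$z[per_gene_a$stage == st]
    zb <- per_gene_b$z[per_gene_b$stage == st]
    if (length(za) == 0L || length(zb) == 0L) return(NULL)
    ba <- bootstrap_mean(za, n_boot = n_boot)
    bb <- bootstrap_mean(zb, n_boot = n_boot)
    data.frame(stage = st,
               mean_a = ba$point_estimate, lo_a = ba$ci_low, hi_a = ba$ci_high,
               mean_b = bb$point_estimate, lo_b = bb$ci_low, hi_b = bb$ci_high,
               a_outside_b = ba$point_estimate < bb$ci_low |
                 ba$point_estimate > bb$ci_high,
               b_outside_a = bb$point_estimate < ba$ci_low |
                 bb$point_estimate > ba$ci_high)
  }))
  rownames(out) <- NULL
  out
}

#' Partition male neo-sex-chromosome reads into neo-X and neo-Y components
#'
#' For genes on the neo-sex chromosome, male reads carrying neo-divergence
#' SNPs split into the maternally inherited neo-X and the paternally
#' inherited neo-Y. Genes without neo-divergence SNPs cannot be
#' partitioned but are retained in the combined neo-XY totals.
#'
#' @param allele an [allele_counts] table.
#' @param ann a [gene_annotation].
#' @param sheet a [sample_sheet].
#' @return data.frame per (gene, male sample): `neoX_reads`, `neoY_reads`,
#'   `neoX_level`, `neoY_level` (shares of the partitionable total, `NA`
#'   when not partitionable), `combined_reads`.
#' @export
partition_neo_alleles <- function(allele, ann, sheet) {
  stopifnot(inherits(allele, "allele_counts"), inherits(ann, "gene_annotation"),
            inherits(sheet, "sample_sheet"))
  neo_genes <- ann$gene_id[ann$chromosome == "Chr3_neoXY"]
  males <- sheet$sample_id[sheet$sex == "male"]
  a <- allele[allele$gene_id %in% neo_genes & allele$sample_id %in% males, ,
              drop = FALSE]
  tot_part <- a$neoX_reads + a$neoY_reads
  out <- data.frame(
    gene_id = a$gene_id, sample_id = a$sample_id,
    neoX_reads = a$neoX_reads, neoY_reads = a$neoY_reads,
    neoX_level = ifelse(!is.na(tot_part) & tot_part > 0,
                        a$neoX_reads / tot_part, NA_real_),
    neoY_level = ifelse(!is.na(tot_part) & tot_part > 0,
                        a$neoY_reads / tot_part, NA_real_),
    combined_reads = a$maternal_reads + a$paternal_reads,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Female:male bias on the neo-sex chromosome stratified by neo-Y ORF status
#'
#' Summarizes female:male ratios per stage for genes whose neo-Y copy has an
#' intact versus a broken open reading frame (functionally hemizygous in
#' males), and tests the strata against each other and against the older X
#' chromosomes with two-sided Wilcoxon rank-sum tests. In
#' `"combined_neoXY"` mode the ratios should come from expression in which
#' male neo-XY reads include both gene copies; `"neoX_only"` mode expects
#' male expression restricted to the neo-X component (e.g. male means
#' multiplied by the per-gene neo-X share from
#' [partition_neo_alleles()]).
#'
#' @param bias a `bias_table` covering the stages of interest (row-bound
#'   [fm_ratio()] outputs).
#' @param ann a [gene_annotation] with `neoY_orf` calls.
#' @param mode `"combined_neoXY"` or `"neoX_only"` (recorded in the output;
#'   the caller supplies the matching expression values).
#' @param min_stratum minimum genes per stratum before flagging (default 5).
#' @return list: `summary` (per stage and stratum: n, mean, median ratio),
#'   `tests` (per stage: intact-vs-broken Wilcoxon p; neo-vs-X Wilcoxon p
#'   when X-linked ratios are present in `bias`), `mode`, `flagged` (stage,
#'   stratum rows under `min_stratum`).
#' @export
orf_stratified_bias <- function(bias, ann, mode = c("combined_neoXY", "neoX_only"),
                                min_stratum = 5L) {
  mode <- match.arg(mode)
  stopifnot(inherits(bias, "bias_table"), inherits(ann, "gene_annotation"))
  b <- bias[bias$included, , drop = FALSE]
  b$chromosome <- ann$chromosome[match(b$gene_id, ann$gene_id)]
  b$orf <- ann$neoY_orf[match(b$gene_id, ann$gene_id)]
  neo <- b[b$chromosome == "Chr3_neoXY" & b$orf %in% c("intact", "broken"), ,
           drop = FALSE]
  x <- b[b$chromosome %in% c("XL", "XR"), , drop = FALSE]
  stages <- sort(unique(b$stage))
  summary <- do.call(rbind, lapply(stages, function(st) {
    do.call(rbind, lapply(c("intact", "broken"), function(o) {
      r <- neo$ratio[neo$stage == st & neo$orf == o]
      data.frame(stage = st, stratum = o, n = length(r),
                 mean_ratio = if (length(r)) mean(r) else NA_real_,
                 median_ratio = if (length(r)) stats::median(r) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  tests <- do.call(rbind, lapply(stages, function(st) {
    ri <- neo$ratio[neo$stage == st & neo$orf == "intact"]
    rb <- neo$ratio[neo$stage == st & neo$orf == "broken"]
    rx <- x$ratio[x$stage == st]
    p_orf <- if (length(ri) > 0L && length(rb) > 0L) {
      wilcoxon_compare(ri, rb)$p_value
    } else NA_real_
    p_neo_vs_x <- if (length(rx) > 0L && length(c(ri, rb)) > 0L) {
      wilcoxon_compare(c(ri, rb), rx)$p_value
    } else NA_real_
    data.frame(stage = st, p_intact_vs_broken = p_orf,
               p_neo_vs_x = p_neo_vs_x)
  }))
  flagged <- summary[summary$n < min_stratum, c("stage", "stratum"), drop = FALSE]
  list(summary = summary, tests = tests, mode = mode, flagged = flagged)
}
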