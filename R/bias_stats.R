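#' Female:male expression ratios per gene at one stage
#'
#' Ratios of sex mean RPKM, restricted to genes whose means exceed
#' `rpkm_min` in both sexes (which also rules out zero denominators, so no
#' pseudocounts are used). When zygotic calls are supplied, only genes
#' called zygotic (at that stage for stage-specific definitions, per gene
#' otherwise) are marked `included`.
#'
#' @param expr an [expression_table] (normalized).
#' @param sheet a [sample_sheet].
#' @param stage ordinal stage (1..8).
#' @param zygotic_calls optional `zygotic_calls` restriction.
#' @param rpkm_min inclusion threshold on both sex means (default 5).
#' @return data.frame of class `bias_table`: `gene_id`, `stage`,
#'   `female_mean`, `male_mean`, `ratio` (`NA` unless included),
#'   `included`.
#' @export
fm_ratio <- function(expr, sheet, stage, zygotic_calls = NULL, rpkm_min = 5) {
  stopifnot(inherits(expr, "expression_table"), inherits(sheet, "sample_sheet"))
  fem <- sheet$sample_id[sheet$stage == stage & sheet$sex == "female"]
  mal <- sheet$sample_id[sheet$stage == stage & sheet$sex == "male"]
  if (length(fem) == 0L || length(mal) == 0L) {
    warning("stage ", stage, " lacks samples of one sex; skipped")
    return(structure(data.frame(gene_id = character(), stage = integer(),
                                female_mean = numeric(), male_mean = numeric(),
                                ratio = numeric(), included = logical()),
                     class = c("bias_table", "data.frame")))
  }
  f <- rowMeans(expr$values[, fem, drop = FALSE])
  m <- rowMeans(expr$values[, mal, drop = FALSE])
  included <- f > rpkm_min & m > rpkm_min
  if (!is.null(zygotic_calls)) {
    stopifnot(inherits(zygotic_calls, "zygotic_calls"))
    if (zygotic_calls$definition == "transcript_level") {
      zy <- zygotic_calls$zygotic[rownames(expr$values)]
    } else {
      zy <- zygotic_calls$calls[rownames(expr$values), stage]
    }
    included <- included & !is.na(zy) & zy
  }
  out <- data.frame(gene_id = rownames(expr$values), stage = stage,
                    female_mean = f, male_mean = m,
                    ratio = ifelse(included, f / m, NA_real_),
                    included = included, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Sex-bias classes
#'
#' Partitions the positive ratio axis at fixed cut points into
#' `male_biased` (< 0.8), `unbiased` (0.8-1.25), `female_1.25_1.5`,
#' `female_1.5_2` and `female_gt2`. The 1.5x and 2x cut points are the
#' operative female-bias thresholds used throughout; the intermediate bins
#' are display conveniences and fully configurable.
#'
#' @param ratio numeric vector of female:male ratios.
#' @param cuts numeric cut points, default `c(0.8, 1.25, 1.5, 2)`.
#' @return factor of class labels.
#' @export
bias_class <- function(ratio, cuts = c(0.8, 1.25, 1.5, 2)) {
  stopifnot(length(cuts) == 4L, !is.unsorted(cuts))
  labels <- c("male_biased", "unbiased", "female_1.25_1.5",
              "female_1.5_2", "female_gt2")
  cut(ratio, breaks = c(0, cuts, Inf), labels = labels, right = TRUE)
}

#' Per-chromosome, per-stage sex-bias class proportions
#'
#' @param bias a `bias_table` (from [fm_ratio()], possibly several stages
#'   row-bound).
#' @param ann a [gene_annotation].
#' @param cuts cut points passed to [bias_class()].
#' @return data.frame: chromosome, stage, class, n, proportion (proportions
#'   sum to 1 within chromosome x stage).
#' @export
classify_bias <- function(bias, ann, cuts = c(0.8, 1.25, 1.5, 2)) {
  stopifnot(inherits(bias, "bias_table"), inherits(ann, "gene_annotation"))
  b <- bias[bias$included, , drop = FALSE]
  b$chromosome <- ann$chromosome[match(b$gene_id, ann$gene_id)]
  b$class <- bias_class(b$ratio, cuts)
  tab <- as.data.frame(table(chromosome = b$chromosome, stage = b$stage,
                             class = b$class), stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  totals <- stats::aggregate(n ~ chromosome + stage, data = tab, FUN = sum)
  tab$proportion <- tab$n / totals$n[match(paste(tab$chromosome, tab$stage),
                                           paste(totals$chromosome, totals$stage))]
  tab[tab$n > 0 | !is.na(tab$proportion), , drop = FALSE]
}

#' Chi-squared comparison of female-biased gene proportions at a cutoff
#'
#' 2x2 test (above/below cutoff x group), df = 1, without continuity
#' correction by default.
#'
#' @param ratios_a,ratios_b numeric ratio vectors for the two groups.
#' @param cutoff female-bias cutoff (e.g. 1.5 to 2).
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list: `statistic`, `p_value`, `table`, `warning` (set when an
#'   expected cell is below 1).
#' @export
chisq_cutoff_compare <- function(ratios_a, ratios_b, cutoff, correct = FALSE) {
  ratios_a <- ratios_a[!is.na(ratios_a)]
  ratios_b <- ratios_b[!is.na(ratios_b)]
  if (length(ratios_a) == 0L || length(ratios_b) == 0L) {
    stop("both groups must be nonempty")
  }
  tab <- rbind(A = c(above = sum(ratios_a > cutoff), below = sum(ratios_a <= cutoff)),
               B = c(above = sum(ratios_b > cutoff), below = sum(ratios_b <= cutoff)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  warn <- if (any(expected < 1)) "expected cell count below 1" else NA_character_
  if (any(colSums(tab) == 0)) {
    # degenerate margin: no information against equality of proportions
    return(list(statistic = 0, p_value = 1, table = tab, warning = warn))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       table = tab, warning = warn)
}

#' Chi-squared scan over a grid of female-bias cutoffs
#'
#' @param bias_a,bias_b `bias_table`s for the two groups (one stage each).
#' @param cutoffs cutoff grid (default `seq(1.5, 2, by = 0.1)`).
#' @param correct Yates correction flag.
#' @return data.frame per cutoff: counts above per group, chi-squared
#'   statistic, raw p, and a Benjamini-Hochberg adjusted column.
#' @export
chisq_cutoff_scan <- function(bias_a, bias_b, cutoffs = seq(1.5, 2, by = 0.1),
                              correct = FALSE) {
  ra <- bias_a$ratio[bias_a$included]
  rb <- bias_b$ratio[bias_b$included]
  out <- do.call(rbind, lapply(cutoffs, function(cu) {
    r <- chisq_cutoff_compare(ra, rb, cu, correct = correct)
    data.frame(cutoff = cu,
               n_a = length(ra), above_a = sum(ra > cu),
               n_b = length(rb), above_b = sum(rb > cu),
               statistic = r$statistic, p_value = r$p_value)
  }))
  out$p_adjust_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact null enumeration when both groups have at most `exact_max`
#' observations and there are no ties; normal approximation with tie
#' correction (no continuity correction) otherwise.
#'
#' @param values_a,values_b numeric vectors.
#' @param exact_max exact-test size limit per group (default 10).
#' @return list: `statistic` (rank-sum W for group A), `p_value`, `exact`.
#' @export
wilcoxon_compare <- function(values_a, values_b, exact_max = 10) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must contain at least one value")
  }
  pooled <- c(values_a, values_b)
  if (all(pooled == pooled[1])) {
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p_value = 1, exact = FALSE))
  }
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- !ties && length(values_a) <= exact_max && length(values_b) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            exact = use_exact,
                                            correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = min(1, unname(wt$p.value)),
       exact = use_exact)
}

spearman_safe <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Stage-correspondence analysis between two timecourses
#'
#' Spearman rank correlations between per-stage mean expression vectors of
#' two datasets over shared genes, with a gene-resampling bootstrap on each
#' diagonal (same-stage) entry and a row p-value: the fraction of bootstrap
#' replicates in which the row's best off-diagonal correlation exceeds its
#' diagonal correlation. Small row p-values indicate that some other stage
#' matches significantly better than the morphologically homologous one.
#'
#' @param expr_a,expr_b [expression_table]s.
#' @param sheet_a,sheet_b matching [sample_sheet]s.
#' @param gene_map optional two-column orthology data.frame (ids in A, ids
#'   in B); identity by default.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list: `correlation` (stage x stage matrix, A rows, B columns),
#'   `diagonal` (per-stage [bootstrap_result]s), `row_p` (per-stage
#'   p-values), `n_genes`.
#' @export
stage_correspondence <- function(expr_a, expr_b, sheet_a, sheet_b,
                                 gene_map = NULL, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(expr_a, "expression_table"), inherits(expr_b, "expression_table"))
  if (!is.null(seed)) set.seed(seed)
  a_genes <- rownames(expr_a$values)
  if (is.null(gene_map)) {
    gene_map <- data.frame(a = a_genes, b = a_genes, stringsAsFactors = FALSE)
  }
  gene_map <- gene_map[gene_map[[1]] %in% a_genes &
                         gene_map[[2]] %in% rownames(expr_b$values), , drop = FALSE]
  n <- nrow(gene_map)
  if (n < 50L) stop("need at least 50 shared genes, have ", n)
  stage_mean <- function(expr, sheet) {
    m <- vapply(seq_len(N_STAGES), function(st) {
      ss <- sheet$sample_id[sheet$stage == st]
      if (length(ss) == 0L) return(rep(NA_real_, nrow(expr$values)))
      rowMeans(expr$values[, ss, drop = FALSE])
    }, numeric(nrow(expr$values)))
    rownames(m) <- rownames(expr$values)
    m
  }
  ma <- stage_mean(expr_a, sheet_a)[gene_map[[1]], , drop = FALSE]
  mb <- stage_mean(expr_b, sheet_b)[gene_map[[2]], , drop = FALSE]
  corr <- matrix(NA_real_, N_STAGES, N_STAGES,
                 dimnames = list(paste0("A", seq_len(N_STAGES)),
                                 paste0("B", seq_len(N_STAGES))))
  for (i in seq_len(N_STAGES)) for (j in seq_len(N_STAGES)) {
    if (!anyNA(ma[, i]) && !anyNA(mb[, j])) corr[i, j] <- spearman_safe(ma[, i], mb[, j])
  }
  diagonal <- vector("list", N_STAGES)
  row_p <- rep(NA_real_, N_STAGES)
  for (st in seq_len(N_STAGES)) {
    if (is.na(corr[st, st])) next
    boot_diag <- numeric(n_boot)
    boot_exceed <- logical(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      row_cor <- vapply(seq_len(N_STAGES), function(j) {
        if (anyNA(mb[, j])) NA_real_ else spearman_safe(ma[idx, st], mb[idx, j])
      }, numeric(1))
      boot_diag[b] <- row_cor[st]
      off <- row_cor[-st]
      boot_exceed[b] <- any(off > row_cor[st], na.rm = TRUE)
    }
    q <- stats::quantile(boot_diag, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    diagonal[[st]] <- bootstrap_result(corr[st, st], q[1], q[2], n_boot)
    row_p[st] <- mean(boot_exceed)
  }
  list(correlation = corr, diagonal = diagonal, row_p = row_p, n_genes = n)
}
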