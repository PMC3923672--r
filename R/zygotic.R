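#' Zygotic-gene calls, allele-specific definition
#'
#' A gene is called zygotically transcribed at a stage when its mean female
#' RPKM exceeds `rpkm_min` (strictly) and the paternal allele carries
#' strictly more than `paternal_min_fraction` of its female reads.
#' Females are used because males have no paternal X. Calls are made
#' independently per stage; genes without female allele data at a stage are
#' not callable there (`NA`, distinct from a negative call).
#'
#' @param expr an [expression_table] (normalized).
#' @param fractions an `allele_fractions` data.frame from
#'   [allele_fractions()].
#' @param sheet a [sample_sheet].
#' @param rpkm_min minimum mean female RPKM (default 5, strict).
#' @param paternal_min_fraction minimum female paternal read fraction
#'   (default 0.40, strict).
#' @param per_embryo_vote if `TRUE`, threshold per embryo and require a
#'   majority instead of thresholding stage means (default `FALSE`).
#' @return object of class `zygotic_calls`: list with `definition`,
#'   `calls` (gene x stage logical matrix, `NA` = not callable),
#'   `thresholds`.
#' @export
call_allele_specific <- function(expr, fractions, sheet,
                                 rpkm_min = 5, paternal_min_fraction = 0.40,
                                 per_embryo_vote = FALSE) {
  stopifnot(inherits(expr, "expression_table"), inherits(sheet, "sample_sheet"))
  genes <- rownames(expr$values)
  stages <- sort(unique(sheet$stage))
  calls <- matrix(NA, length(genes), N_STAGES,
                  dimnames = list(genes, as.character(seq_len(N_STAGES))))
  fr <- fractions[!is.na(fractions$p), , drop = FALSE]
  fr$sex <- sheet$sex[match(fr$sample_id, sheet$sample_id)]
  fr$stage <- sheet$stage[match(fr$sample_id, sheet$sample_id)]
  fr <- fr[fr$sex == "female", , drop = FALSE]
  for (st in stages) {
    fem <- sheet$sample_id[sheet$stage == st & sheet$sex == "female"]
    if (length(fem) == 0L) next
    mean_rpkm <- rowMeans(expr$values[, fem, drop = FALSE])
    sub <- fr[fr$stage == st, , drop = FALSE]
    if (nrow(sub) == 0L) next
    if (per_embryo_vote) {
      vote <- stats::aggregate(
        cbind(ok = sub$p > paternal_min_fraction) ~ gene_id, data = sub, FUN = mean)
      p_ok <- stats::setNames(vote$ok > 0.5, vote$gene_id)
    } else {
      pm <- stats::aggregate(p ~ gene_id, data = sub, FUN = mean)
      p_ok <- stats::setNames(pm$p > paternal_min_fraction, pm$gene_id)
    }
    covered <- intersect(genes, names(p_ok))
    calls[covered, st] <- mean_rpkm[covered] > rpkm_min & p_ok[covered]
  }
  structure(list(definition = "allele_specific", calls = calls,
                 thresholds = c(rpkm_min = rpkm_min,
                                paternal_min_fraction = paternal_min_fraction)),
            class = "zygotic_calls")
}

#' Zygotic-gene calls, transcript-level definition
#'
#' A gene is zygotic when it shows no maternal deposition (mean RPKM
#' strictly below `rpkm_min` at the first sampled stage) and rises strictly
#' above `rpkm_min` at one or more subsequent stages. Sex-agnostic and
#' per-gene (not per-stage); needs no allele data, which makes it the
#' definition of choice when the downstream quantity is itself
#' allele-specific.
#'
#' @param expr an [expression_table].
#' @param sheet a [sample_sheet].
#' @param rpkm_min RPKM threshold (default 5).
#' @param sustained if `TRUE`, require all stages after the first crossing
#'   to stay above threshold (default `FALSE`: any later stage suffices).
#' @return a `zygotic_calls` object; `calls` is gene x stage, TRUE from the
#'   first above-threshold stage onward for zygotic genes; the per-gene
#'   flag is in `zygotic`.
#' @export
call_transcript_level <- function(expr, sheet, rpkm_min = 5, sustained = FALSE) {
  stopifnot(inherits(expr, "expression_table"), inherits(sheet, "sample_sheet"))
  first_stage <- min(sheet$stage)
  s1 <- sheet$sample_id[sheet$stage == first_stage]
  if (length(s1) == 0L) stop("no samples at the first stage")
  stage_means <- vapply(seq_len(N_STAGES), function(st) {
    ss <- sheet$sample_id[sheet$stage == st]
    if (length(ss) == 0L) return(rep(NA_real_, nrow(expr$values)))
    rowMeans(expr$values[, ss, drop = FALSE])
  }, numeric(nrow(expr$values)))
  rownames(stage_means) <- rownames(expr$values)
  no_maternal <- stage_means[, first_stage] < rpkm_min
  later <- stage_means[, setdiff(seq_len(N_STAGES), first_stage), drop = FALSE]
  high_later <- if (sustained) {
    apply(later, 1, function(v) {
      i <- which(!is.na(v) & v > rpkm_min)
      length(i) > 0L && all(v[seq(min(i), length(v))] > rpkm_min, na.rm = TRUE)
    })
  } else rowSums(later > rpkm_min, na.rm = TRUE) > 0L
  zygotic <- no_maternal & high_later
  calls <- stage_means > rpkm_min
  calls[!zygotic, ] <- FALSE
  calls[, first_stage] <- FALSE
  colnames(calls) <- as.character(seq_len(N_STAGES))
  structure(list(definition = "transcript_level", calls = calls,
                 zygotic = zygotic,
                 thresholds = c(rpkm_min = rpkm_min)),
            class = "zygotic_calls")
}

#' First stage at which each gene is called zygotic
#'
#' @param calls a `zygotic_calls` object (stage-specific calls).
#' @return named integer vector: earliest stage with a positive call, `NA`
#'   for genes never called.
#' @export
first_zygotic_stage <- function(calls) {
  stopifnot(inherits(calls, "zygotic_calls"))
  apply(calls$calls, 1, function(v) {
    i <- which(!is.na(v) & v)
    if (length(i) == 0L) NA_integer_ else min(i)
  })
}

#' Intersect zygotic calls from two datasets
#'
#' Restricts calls to genes classified as zygotic in both inputs at each
#' stage, mapping gene identifiers through an orthology table when the two
#' datasets use different gene universes.
#'
#' @param calls_a,calls_b `zygotic_calls` objects.
#' @param gene_map optional two-column data.frame mapping `calls_a` gene ids
#'   (column 1) to `calls_b` gene ids (column 2); identity by default.
#' @return a `zygotic_calls` object in the `calls_a` gene universe; genes
#'   with no ortholog are dropped (count reported via message).
#' @export
intersect_calls <- function(calls_a, calls_b, gene_map = NULL) {
  stopifnot(inherits(calls_a, "zygotic_calls"), inherits(calls_b, "zygotic_calls"))
  a_genes <- rownames(calls_a$calls)
  if (is.null(gene_map)) {
    gene_map <- data.frame(a = a_genes, b = a_genes, stringsAsFactors = FALSE)
  }
  map <- stats::setNames(as.character(gene_map[[2]]), as.character(gene_map[[1]]))
  b_of_a <- map[a_genes]
  keep <- !is.na(b_of_a) & b_of_a %in% rownames(calls_b$calls)
  n_drop <- sum(!keep)
  if (n_drop > 0L) message(n_drop, " gene(s) without ortholog dropped")
  a <- calls_a$calls[keep, , drop = FALSE]
  b <- calls_b$calls[b_of_a[keep], , drop = FALSE]
  inter <- a & b
  if (all(!inter, na.rm = TRUE)) warning("empty intersection of zygotic calls")
  structure(list(definition = paste0(calls_a$definition, "_intersect"),
                 calls = inter, thresholds = calls_a$thresholds),
            class = "zygotic_calls")
}
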