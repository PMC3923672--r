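#' Compensation labels from female:male ratios
#'
#' A gene counts as compensated at a stage when its female:male ratio is
#' below the threshold (default 1.5x), uncompensated when above it; genes
#' failing the >5 RPKM inclusion rule in either sex are excluded.
#'
#' @param bias a `bias_table` (row-bound [fm_ratio()] outputs).
#' @param threshold female-bias threshold (default 1.5).
#' @return data.frame: `gene_id`, `stage`, `ratio`, `label` in
#'   `compensated` / `uncompensated` / `excluded`.
#' @export
compensation_labels <- function(bias, threshold = 1.5) {
  stopifnot(inherits(bias, "bias_table"))
  lab <- ifelse(!bias$included, "excluded",
                ifelse(bias$ratio < threshold, "compensated", "uncompensated"))
  data.frame(gene_id = bias$gene_id, stage = bias$stage, ratio = bias$ratio,
             label = lab, stringsAsFactors = FALSE)
}

#' Mean nearest-neighbour distance among gene positions
#'
#' For each position, the distance (bp) to the nearest other position in
#' the same set; returns their mean. Translation-invariant and linear in
#' coordinate scale.
#'
#' @param positions numeric vector of gene positions on one chromosome
#'   (at least 2).
#' @return mean nearest-neighbour distance.
#' @export
nn_distance_stat <- function(positions) {
  n <- length(positions)
  if (n < 2L) stop("need at least 2 positions")
  s <- sort(positions)
  gaps <- diff(s)
  nn <- pmin(c(Inf, gaps), c(gaps, Inf))
  mean(nn)
}

#' Permutation test for spatial clustering of a labelled gene set
#'
#' Compares the observed mean nearest-neighbour distance of a labelled gene
#' set against a null built by repeatedly drawing the same number of genes
#' without replacement from a null universe on the same chromosome. The
#' empirical p-value is left-tailed (small distances = clustering) with the
#' add-one convention, so p is never exactly zero. Because zygotically
#' transcribed genes are themselves closer together than arbitrary genes,
#' the null universe should normally be the zygotic genes at that stage;
#' drawing from all genes is supported to expose that contrast.
#'
#' @param positions positions of the labelled genes.
#' @param universe_positions positions of the null universe (must contain at
#'   least `length(positions)` entries).
#' @param n_reps null draws (default 1000).
#' @param seed RNG seed.
#' @return list: `observed`, `p_value`, `n_reps`.
#' @export
nn_clustering_test <- function(positions, universe_positions,
                               n_reps = 1000, seed = NULL) {
  if (length(positions) < 2L) stop("need at least 2 labelled positions")
  if (length(universe_positions) < length(positions)) {
    stop("labelled set larger than null universe")
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- nn_distance_stat(positions)
  k <- length(positions)
  null <- vapply(seq_len(n_reps), function(i) {
    nn_distance_stat(sample(universe_positions, k))
  }, numeric(1))
  p <- (1 + sum(null <= obs)) / (n_reps + 1)
  list(observed = obs, p_value = p, n_reps = n_reps)
}

#' Clustering tests for compensated/uncompensated genes per chromosome
#'
#' Runs [nn_clustering_test()] for each (stage, chromosome, label)
#' combination, with the null universe drawn either from the zygotic genes
#' of that stage (`"zygotic"`) or from all annotated genes on the
#' chromosome (`"all"`). Gene position is the start coordinate (midpoint by
#' flag).
#'
#' @param labels output of [compensation_labels()].
#' @param ann a [gene_annotation].
#' @param zygotic_genes character vector (or per-stage list) of zygotic gene
#'   ids defining the `"zygotic"` universe.
#' @param null_universe `"zygotic"` or `"all"`.
#' @param n_reps,seed passed to [nn_clustering_test()].
#' @param use_midpoint use the gene midpoint instead of the start.
#' @return data.frame: stage, chromosome, label, n, observed mean NN
#'   distance, p_value.
#' @export
clustering_test <- function(labels, ann, zygotic_genes,
                            null_universe = c("zygotic", "all"),
                            n_reps = 1000, seed = NULL,
                            use_midpoint = FALSE) {
  null_universe <- match.arg(null_universe)
  stopifnot(inherits(ann, "gene_annotation"))
  if (!is.null(seed)) set.seed(seed)
  pos_of <- if (use_midpoint) (ann$start + ann$end) / 2 else ann$start
  names(pos_of) <- ann$gene_id
  chrom_of <- stats::setNames(ann$chromosome, ann$gene_id)
  out <- list()
  for (st in sort(unique(labels$stage))) {
    zyg_st <- if (is.list(zygotic_genes)) zygotic_genes[[as.character(st)]] else zygotic_genes
    for (ch in unique(ann$chromosome)) {
      universe_genes <- if (null_universe == "zygotic") {
        intersect(zyg_st, ann$gene_id[ann$chromosome == ch])
      } else ann$gene_id[ann$chromosome == ch]
      for (lab in c("compensated", "uncompensated")) {
        genes <- labels$gene_id[labels$stage == st & labels$label == lab &
                                  chrom_of[labels$gene_id] == ch]
        if (length(genes) < 2L || length(universe_genes) < length(genes)) next
        r <- nn_clustering_test(pos_of[genes], pos_of[universe_genes],
                                n_reps = n_reps)
        out[[length(out) + 1L]] <- data.frame(
          stage = st, chromosome = ch, label = lab, n = length(genes),
          observed = r$observed, p_value = r$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## distance from each position to the nearest interval [start, end); 0 inside
dist_to_intervals <- function(pos, starts, ends) {
  vapply(pos, function(p) {
    d <- ifelse(p >= starts & p < ends, 0, pmin(abs(p - starts), abs(p - (ends - 1L))))
    min(d)
  }, numeric(1))
}

#' Sex-ratio association with proximity to high-affinity sites
#'
#' Computes each gene's distance (gene start, bp) to the nearest
#' high-affinity site interval, pooled over chromosomes by default, splits
#' genes at the 25th percentile of distance (ties included in the lower
#' quartile), and compares female:male ratios between the lower quartile
#' and the upper three quartiles with a two-sided Wilcoxon rank-sum test,
#' per stage. If high-affinity sites seed the spreading of the
#' dosage-compensation machinery, nearby genes would be expected to look
#' more compensated (lower ratios).
#'
#' @param bias a `bias_table`.
#' @param has data.frame of site intervals: `chromosome`, `start`, `end`
#'   (0-based half-open; strand irrelevant). May also be a `GRanges`.
#' @param ann a [gene_annotation].
#' @param per_chromosome analyse each chromosome separately instead of
#'   pooled (default `FALSE`).
#' @param min_genes minimum included genes per test (default 8).
#' @return data.frame per stage (and chromosome if `per_chromosome`):
#'   `n`, `n_near`, `mean_ratio_near`, `mean_ratio_far`, `p_value`.
#' @export
has_proximity_test <- function(bias, has, ann, per_chromosome = FALSE,
                               min_genes = 8L) {
  stopifnot(inherits(bias, "bias_table"), inherits(ann, "gene_annotation"))
  if (inherits(has, "GRanges")) {
    has <- data.frame(chromosome = as.character(GenomicRanges::seqnames(has)),
                      start = GenomicRanges::start(has) - 1L,
                      end = GenomicRanges::end(has), stringsAsFactors = FALSE)
  }
  b <- bias[bias$included, , drop = FALSE]
  b$chromosome <- ann$chromosome[match(b$gene_id, ann$gene_id)]
  b$pos <- ann$start[match(b$gene_id, ann$gene_id)]
  b <- b[b$chromosome %in% unique(has$chromosome), , drop = FALSE]
  b$dist <- NA_real_
  for (ch in unique(b$chromosome)) {
    hi <- has[has$chromosome == ch, , drop = FALSE]
    sel <- b$chromosome == ch
    b$dist[sel] <- dist_to_intervals(b$pos[sel], hi$start, hi$end)
  }
  groups <- if (per_chromosome) split(b, b$chromosome) else list(pooled = b)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    bb <- groups[[g]]
    do.call(rbind, lapply(sort(unique(bb$stage)), function(st) {
      s <- bb[bb$stage == st, , drop = FALSE]
      if (nrow(s) < min_genes) return(NULL)
      if (length(unique(s$dist)) == 1L) {
        return(data.frame(group = g, stage = st, n = nrow(s), n_near = nrow(s),
                          mean_ratio_near = mean(s$ratio),
                          mean_ratio_far = NA_real_, p_value = NA_real_,
                          stringsAsFactors = FALSE))
      }
      q1 <- stats::quantile(s$dist, 0.25, names = FALSE, type = 7)
      near <- s$dist <= q1   # ties join the lower quartile
      p <- wilcoxon_compare(s$ratio[near], s$ratio[!near])$p_value
      data.frame(group = g, stage = st, n = nrow(s), n_near = sum(near),
                 mean_ratio_near = mean(s$ratio[near]),
                 mean_ratio_far = mean(s$ratio[!near]), p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' H4K16ac enrichment of compensated versus uncompensated genes
#'
#' Mean per-gene H4K16ac enrichment for each compensation label with
#' gene-resampling bootstrap CIs; a label is flagged when its mean falls
#' outside the other label's 95% CI, in either direction (more-enriched and
#' less-enriched are both informative: late-stage compensated genes are
#' expected to be MSL targets, early-stage compensated genes need not be).
#'
#' @param labels output of [compensation_labels()] (one or more stages).
#' @param enrichment named numeric vector of per-gene enrichment values.
#' @param ann optional [gene_annotation]; when given, results are reported
#'   per chromosome as well as pooled.
#' @param n_boot,seed bootstrap parameters.
#' @return data.frame per (stage, chromosome-or-pooled): per-label n,
#'   mean, CI, and `compensated_outside` / `uncompensated_outside` flags
#'   with direction (`above` / `below` / `no`).
#' @export
h4k16ac_compare <- function(labels, enrichment, ann = NULL,
                            n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  l <- labels[labels$label %in% c("compensated", "uncompensated"), , drop = FALSE]
  l$enrich <- enrichment[l$gene_id]
  l <- l[!is.na(l$enrich), , drop = FALSE]
  l$chromosome <- if (is.null(ann)) "pooled" else
    ann$chromosome[match(l$gene_id, ann$gene_id)]
  scopes <- unique(c("pooled", unique(l$chromosome)))
  if (is.null(ann)) scopes <- "pooled"
  out <- list()
  for (st in sort(unique(l$stage))) {
    for (sc in scopes) {
      s <- l[l$stage == st & (sc == "pooled" | l$chromosome == sc), , drop = FALSE]
      ec <- s$enrich[s$label == "compensated"]
      eu <- s$enrich[s$label == "uncompensated"]
      if (length(ec) == 0L || length(eu) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          stage = st, scope = sc, n_comp = length(ec), n_uncomp = length(eu),
          mean_comp = if (length(ec)) mean(ec) else NA_real_,
          mean_uncomp = if (length(eu)) mean(eu) else NA_real_,
          lo_comp = NA_real_, hi_comp = NA_real_,
          lo_uncomp = NA_real_, hi_uncomp = NA_real_,
          compensated_outside = NA_character_,
          uncompensated_outside = NA_character_, stringsAsFactors = FALSE)
        next
      }
      bc <- bootstrap_mean(ec, n_boot = n_boot)
      bu <- bootstrap_mean(eu, n_boot = n_boot)
      flag <- function(x, other) {
        if (x > other$ci_high) "above" else if (x < other$ci_low) "below" else "no"
      }
      out[[length(out) + 1L]] <- data.frame(
        stage = st, scope = sc, n_comp = length(ec), n_uncomp = length(eu),
        mean_comp = bc$point_estimate, mean_uncomp = bu$point_estimate,
        lo_comp = bc$ci_low, hi_comp = bc$ci_high,
        lo_uncomp = bu$ci_low, hi_uncomp = bu$ci_high,
        compensated_outside = flag(bc$point_estimate, bu),
        uncompensated_outside = flag(bu$point_estimate, bc),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
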