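#' Default simulation configuration for a karyotype profile
#'
#' Three profiles encode the karyotypes under study. `pse_like` carries the
#' ancestral X (XL), the younger XR, and chromosome 3 as an ordinary
#' autosome. `mir_like` shares the karyotype but chromosome 3 is a
#' neo-X/neo-Y pair, about half of whose neo-Y open reading frames are
#' disrupted; zygotic genome activation and the onset of male-X
#' hypertranscription are delayed by one stage. `mel_like` carries a single
#' ancestral X and models the early-zygotic regime in which roughly half of
#' zygotic X-linked genes are fully dose-compensated on a per-gene basis.
#'
#' Defaults: eight ordinal stages, three embryos per sex per stage, lognormal
#' maternal deposition and zygotic per-copy rates (meanlog `log(20)` RPKM,
#' sdlog 1), geometric maternal decay (0.7 retained per stage after the
#' maternal-to-zygotic transition), negative-binomial expression noise
#' (size 20), 200 expected SNP-overlapping reads per typically-expressed
#' gene, and a male-X per-copy compensation trajectory rising from 1 to 2
#' with onset at ordinal stage 5 (`pse_like`) or 6 (`mir_like`).
#'
#' @param profile one of `"pse_like"`, `"mir_like"`, `"mel_like"`.
#' @param seed integer RNG seed stored in the config.
#' @return a `sim_config` list; see the field list in the source and the
#'   methods vignette for units and rationale.
#' @export
default_config <- function(profile = c("pse_like", "mir_like", "mel_like"),
                           seed = 1L) {
  profile <- match.arg(profile)
  n_genes <- switch(profile,
    pse_like = c(Chr2 = 300L, Chr4 = 40L, XL = 200L, XR = 300L, Chr3_neoXY = 300L),
    mir_like = c(Chr2 = 300L, Chr4 = 40L, XL = 200L, XR = 300L, Chr3_neoXY = 300L),
    mel_like = c(Chr2 = 300L, Chr4 = 40L, XL = 400L))
  trajectory <- switch(profile,
    pse_like = c(1, 1, 1, 1, 1.5, 1.75, 2, 2),
    mir_like = c(1, 1, 1, 1, 1, 1.5, 1.75, 2),
    mel_like = c(1, 1, 1, 1, 1, 1, 1, 1))
  cfg <- list(
    profile = profile,
    n_genes_per_chromosome = n_genes,
    n_replicates = 3L,
    # maternal deposition: which genes carry maternal transcript, at what level
    maternal_fraction = 0.7,
    maternal_meanlog = log(20),
    maternal_sdlog = 1,
    maternal_decay_per_stage = 0.7,   # fraction retained per stage after MZT
    mzt_stage = 2L,                   # decay begins after this ordinal stage
    # zygotic transcription
    zygotic_fraction = 0.5,
    zygotic_onset_distribution = c(0, 0.05, 0.55, 0.20, 0.10, 0.10, 0, 0),
    zygotic_rate_meanlog = log(20),   # per-copy RPKM
    zygotic_rate_sdlog = 1,
    species_delay_stages = if (profile == "mir_like") 1L else 0L,
    # male-X per-copy upregulation factor per stage, in [1, 2]
    compensation_trajectory = trajectory,
    # per-gene compensation regime (early-zygotic, mel_like): each zygotic
    # X-linked gene is fully compensated with this probability, at all
    # stages from its onset; NA disables the regime
    per_gene_compensation_prob = if (profile == "mel_like") 0.5 else NA_real_,
    per_gene_compensation_factor = 2,
    # neo-sex chromosome (mir_like only)
    neoY_broken_fraction = 0.5,
    neoY_retention_shape1 = 1.2,      # Beta() of neo-Y:neo-X per-copy output
    neoY_retention_shape2 = 1.8,
    neo_snp_fraction = if (profile == "mir_like") 0.68 else NA_real_,
    # SNP informativeness between parental lines
    snp_informative_fraction = switch(profile, pse_like = 0.92,
                                      mir_like = 0.75, mel_like = 0.9),
    # sequencing model
    read_depth = 200,                 # expected SNP reads for a typical gene
    count_per_rpkm = 10,              # fragment counts per RPKM unit
    noise_model = "negative_binomial",
    nb_size = 20,
    depth_variation_sdlog = 0,        # per-embryo lognormal depth factor
    allelic_imbalance = 0,            # log-odds shift of the paternal allele
    gene_length = 1000L,              # bp; fixed so count<->RPKM is transparent
    cluster_zygotic = FALSE,          # spatial clustering of zygotic genes
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  bad <- setdiff(names(cfg$n_genes_per_chromosome), CHROMOSOMES)
  if (length(bad) > 0L) stop("unknown chromosome key(s) in config: ",
                             paste(bad, collapse = ", "))
  probs <- c(cfg$maternal_fraction, cfg$zygotic_fraction,
             cfg$zygotic_onset_distribution, cfg$snp_informative_fraction,
             cfg$neoY_broken_fraction)
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) stop("probabilities must lie in [0, 1]")
  if (length(cfg$zygotic_onset_distribution) != N_STAGES) {
    stop("zygotic_onset_distribution must have ", N_STAGES, " entries")
  }
  if (abs(sum(cfg$zygotic_onset_distribution) - 1) > 1e-8) {
    stop("zygotic_onset_distribution must sum to 1")
  }
  if (length(cfg$compensation_trajectory) != N_STAGES) {
    stop("compensation_trajectory must have ", N_STAGES, " entries")
  }
  if (is.unsorted(cfg$compensation_trajectory)) {
    stop("compensation_trajectory must be non-decreasing in stage")
  }
  if (any(cfg$compensation_trajectory < 1 | cfg$compensation_trajectory > 2)) {
    stop("compensation_trajectory entries must lie in [1, 2]")
  }
  if (!cfg$noise_model %in% c("poisson", "negative_binomial")) {
    stop("noise_model must be poisson or negative_binomial")
  }
  cfg
}

## negative-binomial (or Poisson) draw around an expected value
rnoise <- function(n, mu, cfg) {
  if (cfg$noise_model == "poisson") stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = cfg$nb_size)
}

#' Simulate a single-embryo timecourse experiment with known ground truth
#'
#' Generates an expression table (RPKM), SNP-level allele counts, sample
#' sheet and gene annotation for one species profile, together with the
#' generative truth for every gene and sample. Expression per gene and
#' sample is a maternal component (identical between sexes, carried entirely
#' by maternal alleles, decaying geometrically after the
#' maternal-to-zygotic transition) plus a zygotic component (zero before the
#' gene's onset stage; per-copy rate times copy number times the sex- and
#' stage-specific compensation factor afterwards), with count noise.
#' SNP-overlapping allele reads track the realized expression and are split
#' maternal:paternal according to the transcript composition: 1:1 for the
#' zygotic part of biallelic genes, all-maternal for maternal transcript and
#' for the male X, and neo-X:neo-Y in males according to the gene's neo-Y
#' retention level.
#'
#' @param config a `sim_config` from [default_config()], possibly modified.
#' @return list of class `sim_experiment` with elements `expr`
#'   ([expression_table]), `allele` ([allele_counts]), `sheet`
#'   ([sample_sheet]), `ann` ([gene_annotation]) and `truth` (list with
#'   `genes` and `samples` data.frames).
#' @export
simulate_experiment <- function(config) {
  cfg <- validate_config(config)
  set.seed(cfg$seed)
  neo_is_sex <- cfg$profile == "mir_like"

  ## ---- genes -------------------------------------------------------------
  chroms <- rep(names(cfg$n_genes_per_chromosome), cfg$n_genes_per_chromosome)
  n_g <- length(chroms)
  gene_id <- sprintf("g_%s_%04d", chroms, unlist(lapply(
    cfg$n_genes_per_chromosome, seq_len)))
  cls <- chromosome_class(chroms, neo_is_sex = neo_is_sex)

  is_maternal <- stats::runif(n_g) < cfg$maternal_fraction
  maternal_level <- ifelse(is_maternal,
                           stats::rlnorm(n_g, cfg$maternal_meanlog, cfg$maternal_sdlog), 0)
  is_zygotic <- stats::runif(n_g) < cfg$zygotic_fraction
  onset <- rep(NA_integer_, n_g)
  onset[is_zygotic] <- sample.int(N_STAGES, sum(is_zygotic), replace = TRUE,
                                  prob = cfg$zygotic_onset_distribution)
  onset <- pmin(onset + cfg$species_delay_stages, N_STAGES)
  zygotic_level <- ifelse(is_zygotic,
                          stats::rlnorm(n_g, cfg$zygotic_rate_meanlog, cfg$zygotic_rate_sdlog), 0)

  comp_gene <- rep(NA, n_g)
  if (!is.na(cfg$per_gene_compensation_prob)) {
    on_x <- cls %in% c("X", "neoXY") & is_zygotic
    comp_gene[on_x] <- stats::runif(sum(on_x)) < cfg$per_gene_compensation_prob
  }

  neoY_orf <- rep("not_applicable", n_g)
  neoY_retention <- rep(NA_real_, n_g)
  if (neo_is_sex) {
    neo <- chroms == "Chr3_neoXY"
    neoY_orf[neo] <- ifelse(stats::runif(sum(neo)) < cfg$neoY_broken_fraction,
                            "broken", "intact")
    neoY_retention[neo] <- stats::rbeta(sum(neo), cfg$neoY_retention_shape1,
                                        cfg$neoY_retention_shape2)
  }

  n_snps <- ifelse(stats::runif(n_g) < cfg$snp_informative_fraction,
                   1L + stats::rpois(n_g, 2), 0L)
  has_neo_snps <- if (neo_is_sex) {
    chroms == "Chr3_neoXY" & stats::runif(n_g) < cfg$neo_snp_fraction
  } else rep(FALSE, n_g)

  ## gene positions: uniform along each chromosome, optionally with zygotic
  ## genes drawn around cluster centres
  start <- integer(n_g)
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    L <- length(idx) * 10000L
    pos <- as.integer(stats::runif(length(idx), 0, L - cfg$gene_length))
    if (cfg$cluster_zygotic && any(is_zygotic[idx])) {
      zi <- which(is_zygotic[idx])
      n_cl <- max(1L, length(zi) %/% 10L)
      centres <- stats::runif(n_cl, 0, L - cfg$gene_length)
      pos[zi] <- as.integer(pmin(pmax(
        centres[sample.int(n_cl, length(zi), replace = TRUE)] +
          stats::rnorm(length(zi), 0, L / 200), 0), L - cfg$gene_length))
    }
    start[idx] <- pos
  }
  ann <- gene_annotation(data.frame(
    gene_id = gene_id, chromosome = chroms, start = start,
    end = start + cfg$gene_length,
    strand = sample(c("+", "-"), n_g, replace = TRUE),
    neoY_orf = neoY_orf, n_informative_snps = n_snps,
    stringsAsFactors = FALSE))

  ## ---- samples -----------------------------------------------------------
  grid <- expand.grid(
    replicate = seq_len(cfg$n_replicates), sex = c("female", "male"),
    stage = seq_len(N_STAGES), stringsAsFactors = FALSE)
  sheet <- sample_sheet(data.frame(
    sample_id = sprintf("%s_s%d_%s_r%d", cfg$profile, grid$stage,
                        substr(grid$sex, 1, 1), grid$replicate),
    species = cfg$profile, stage = grid$stage, sex = grid$sex,
    replicate = grid$replicate, stringsAsFactors = FALSE))
  n_s <- nrow(sheet)
  depth_factor <- if (cfg$depth_variation_sdlog > 0) {
    stats::rlnorm(n_s, 0, cfg$depth_variation_sdlog)
  } else rep(1, n_s)

  ## ---- expected components (genes x samples) ------------------------------
  decay_pow <- pmax(0L, sheet$stage - cfg$mzt_stage)
  mat_e <- outer(maternal_level, cfg$maternal_decay_per_stage^decay_pow)

  active <- outer(onset, sheet$stage, function(o, s) !is.na(o) & s >= o)
  z_rate <- matrix(zygotic_level, n_g, n_s) * active

  is_male <- sheet$sex == "male"
  traj <- cfg$compensation_trajectory[sheet$stage]
  comp <- matrix(rep(traj, each = n_g), n_g, n_s)      # trajectory regime
  if (!is.na(cfg$per_gene_compensation_prob)) {
    pg <- ifelse(is.na(comp_gene), 1,
                 ifelse(comp_gene, cfg$per_gene_compensation_factor, 1))
    comp <- matrix(pg, n_g, n_s)                        # per-gene regime
  }

  zyg_f <- 2 * z_rate                                   # two copies, both sexes
  zyg_m <- matrix(0, n_g, n_s)
  auto <- cls == "autosome"
  zyg_m[auto, ] <- 2 * z_rate[auto, , drop = FALSE]
  xl <- cls == "X"
  zyg_m[xl, ] <- z_rate[xl, , drop = FALSE] * comp[xl, , drop = FALSE]
  neo <- cls == "neoXY"
  zyg_m_neoY <- matrix(0, n_g, n_s)
  if (any(neo)) {
    ret <- matrix(neoY_retention, n_g, n_s)
    zyg_m[neo, ] <- z_rate[neo, , drop = FALSE] * comp[neo, , drop = FALSE] +
      z_rate[neo, , drop = FALSE] * ret[neo, , drop = FALSE]
    zyg_m_neoY[neo, ] <- z_rate[neo, , drop = FALSE] * ret[neo, , drop = FALSE]
  }
  zyg <- zyg_f
  zyg[, is_male] <- zyg_m[, is_male]
  expected <- mat_e + zyg

  ## ---- expression counts -> RPKM ------------------------------------------
  counts <- matrix(rnoise(n_g * n_s, expected * cfg$count_per_rpkm, cfg), n_g, n_s)
  rpkm <- counts / cfg$count_per_rpkm
  dimnames(rpkm) <- list(gene_id, sheet$sample_id)
  expr <- expression_table(rpkm)

  ## ---- allele reads -------------------------------------------------------
  ## expected SNP reads track realized expression, scaled so a typical
  ## two-copy zygotic gene receives read_depth reads
  e_typ <- 2 * exp(cfg$zygotic_rate_meanlog)
  informative <- n_snps >= 1L
  gi <- which(informative)
  mu_t <- sweep(rpkm[gi, , drop = FALSE] / e_typ * cfg$read_depth, 2, depth_factor, `*`)
  total <- matrix(stats::rpois(length(mu_t), mu_t), nrow(mu_t), ncol(mu_t))

  ## true paternal share of the transcript pool, per gene x sample
  frac_zyg <- zyg / pmax(expected, .Machine$double.eps)
  p_pat <- frac_zyg / 2                                 # biallelic zygotic
  if (any(neo)) {
    pn <- matrix(0, n_g, n_s)
    pn[neo, ] <- zyg_m_neoY[neo, , drop = FALSE] /
      pmax(expected[neo, , drop = FALSE], .Machine$double.eps)
    p_pat[neo, is_male] <- pn[neo, is_male]             # paternal = neo-Y
  }
  p_pat[xl, is_male] <- 0                               # male X is maternal
  if (cfg$allelic_imbalance != 0) {
    odds <- p_pat / (1 - p_pat) * exp(cfg$allelic_imbalance)
    p_pat <- ifelse(p_pat %in% c(0, 1), p_pat, odds / (1 + odds))
  }
  p_sub <- p_pat[gi, , drop = FALSE]
  pat <- matrix(stats::rbinom(length(total), total, p_sub), nrow(total), ncol(total))
  mat <- total - pat

  ## SNPs observed: expected occupancy of n_snps urns after `total` reads
  nsnp_m <- matrix(n_snps[gi], nrow(total), ncol(total))
  n_obs <- round(nsnp_m * (1 - (1 - 1 / nsnp_m)^total))
  n_obs[total == 0] <- 0L

  allele <- data.frame(
    gene_id = rep(gene_id[gi], times = n_s),
    sample_id = rep(sheet$sample_id, each = length(gi)),
    maternal_reads = as.vector(mat),
    paternal_reads = as.vector(pat),
    n_snps_observed = as.integer(n_obs),
    neoX_reads = NA_real_, neoY_reads = NA_real_,
    stringsAsFactors = FALSE)
  if (any(neo)) {
    ## neo-divergence SNPs let us split male reads into neo-X (maternally
    ## inherited) and neo-Y (paternally inherited) components
    male_of <- rep(is_male, each = length(gi))
    neo_of <- rep(has_neo_snps[gi], times = n_s)
    sel <- male_of & neo_of
    allele$neoX_reads[sel] <- allele$maternal_reads[sel]
    allele$neoY_reads[sel] <- allele$paternal_reads[sel]
  }
  allele <- allele_counts(allele)

  truth <- list(
    genes = data.frame(
      gene_id = gene_id, chromosome = chroms, class = cls,
      is_maternal = is_maternal, maternal_level = maternal_level,
      is_zygotic = is_zygotic, onset_stage = onset,
      zygotic_level = zygotic_level, comp_gene = comp_gene,
      neoY_orf = neoY_orf, neoY_retention = neoY_retention,
      has_neo_snps = has_neo_snps, n_informative_snps = n_snps,
      stringsAsFactors = FALSE),
    samples = data.frame(
      sample_id = sheet$sample_id, true_sex = sheet$sex,
      true_stage = sheet$stage, depth_factor = depth_factor,
      stringsAsFactors = FALSE),
    config = cfg)

  structure(list(expr = expr, allele = allele, sheet = sheet, ann = ann,
                 truth = truth),
            class = "sim_experiment")
}

#' Write a simulated experiment to a directory of TSV/BED files
#'
#' @param sim a `sim_experiment` from [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  write_allele_counts(sim$allele, file.path(dir, "allele_counts.tsv"))
  write_sample_sheet(sim$sheet, file.path(dir, "sample_sheet.tsv"))
  write_annotation(sim$ann, file.path(dir, "annotation.bed"))
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$samples, file.path(dir, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
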