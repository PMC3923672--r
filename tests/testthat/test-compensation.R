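test_that("bootstrap of a mean handles degenerate inputs and is reproducible", {
  b <- bootstrap_mean(c(5, 5, 5), n_boot = 200, seed = 1)
  expect_equal(b$point_estimate, 5)
  expect_equal(c(b$ci_low, b$ci_high), c(5, 5))
  b1 <- bootstrap_mean(7, n_boot = 100, seed = 2)
  expect_equal(c(b1$ci_low, b1$ci_high), c(7, 7))
  expect_error(bootstrap_mean(numeric(0)), "at least one")
  x <- rnorm(50)
  expect_identical(bootstrap_mean(x, seed = 9)[1:4],
                   bootstrap_mean(x, seed = 9)[1:4])
})

test_that("bootstrap CI coverage for a mean is near 95%", {
  set.seed(123)
  n_sim <- 1000
  covered <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    x <- rnorm(100)
    b <- bootstrap_mean(x, n_boot = 1000)
    covered[i] <- b$ci_low <= 0 && 0 <= b$ci_high
  }
  expect_lt(abs(mean(covered) - 0.95), 0.02)
})

run_onset <- function(cfg, n_boot = 1000) {
  sim <- simulate_experiment(cfg)
  norm <- normalize_autosomal(sim$expr, sim$ann)
  fr <- allele_fractions(sim$allele)
  tl <- call_transcript_level(norm, sim$sheet)
  maternal_allele_onset(fr, sim$sheet, sim$ann,
                        zygotic_genes = rownames(norm$values)[tl$zygotic],
                        n_boot = n_boot,
                        scale_factors = attr(norm, "scale_factors"),
                        neo_is_sex = cfg$profile == "mir_like")
}

onset_config <- function(profile, seed, step_stage = 6L) {
  cfg <- default_config(profile, seed = seed)
  cfg$n_genes_per_chromosome <- c(Chr2 = 150L, Chr4 = 30L, XL = 400L)
  traj <- rep(1, 8)
  if (!is.na(step_stage)) traj[step_stage:8] <- 2
  cfg$compensation_trajectory <- traj
  cfg
}

test_that("a compensation step at stage 6 is detected there and only on the X", {
  rep6 <- run_onset(onset_config("pse_like", seed = 51, step_stage = 6L))
  expect_equal(unname(rep6$onset["X"]), 6L)
  expect_true(is.na(rep6$onset["autosome"]))
})

test_that("flags are rare without compensation", {
  # the one-sided CI-exclusion rule keeps the per-cell false-flag rate low;
  # a single run can still show an occasional flag at the no-signal stages
  rep0 <- run_onset(onset_config("pse_like", seed = 52, step_stage = NA))
  expect_lte(mean(rep0$table$significant), 0.05)
  post <- rep0$table[rep0$table$stage >= 4, ]
  expect_true(all(!post$significant))
})

test_that("the delayed profile shows onset one stage later", {
  # default trajectories place the rise at ordinal 5 (pse-like) and 6
  # (mir-like, one-stage delay)
  rp <- run_onset(default_config("pse_like", seed = 53))
  rm <- run_onset(default_config("mir_like", seed = 53))
  expect_equal(unname(rm$onset["X"] - rp$onset["X"]), 1L)
})

test_that("onset recovery and null false-flag rates meet their targets", {
  # 40 recovery runs + 60 null runs at n_boot 400 keep this block fast;
  # the acceptance suite runs the full 100 + 200 design
  hits <- vapply(1:40, function(i) {
    r <- run_onset(onset_config("pse_like", seed = 1000 + i), n_boot = 400)
    identical(unname(r$onset["X"]), 6L)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  flags <- vapply(1:60, function(i) {
    r <- run_onset(onset_config("pse_like", seed = 2000 + i, step_stage = NA),
                   n_boot = 400)
    mean(r$table$significant)
  }, numeric(1))
  expect_lte(mean(flags), 0.05)
})

test_that("zygotic-fraction comparison flags a developmental delay", {
  per_gene_z <- function(cfg) {
    sim <- simulate_experiment(cfg)
    fr <- allele_fractions(sim$allele)
    zygotic_fraction(fr, sim$sheet, sim$ann,
                     neo_is_sex = cfg$profile == "mir_like")$per_gene
  }
  # same seed: both datasets share gene programs (orthologous genes with
  # conserved parameters); only the activation delay differs
  cfg_a <- small_config("pse_like", seed = 61)
  cfg_b <- small_config("pse_like", seed = 61)
  cfg_b$species_delay_stages <- 1L
  za <- per_gene_z(cfg_a)
  zb <- per_gene_z(cfg_b)
  cmp <- zygotic_fraction_compare(za, zb, n_boot = 500, seed = 3)
  early <- cmp[cmp$stage %in% 3:4, ]
  late <- cmp[cmp$stage == 8, ]
  expect_true(any(early$a_outside_b | early$b_outside_a))
  expect_false(any(late$a_outside_b | late$b_outside_a))
  # identical groups are never flagged
  cmp0 <- zygotic_fraction_compare(za, za, n_boot = 500, seed = 4)
  expect_false(any(cmp0$a_outside_b | cmp0$b_outside_a))
  # a large gap flags in both directions
  expect_true(all(early$a_outside_b == early$b_outside_a))
})

test_that("neo-allele partition splits male reads by inheritance", {
  al <- allele_counts(data.frame(
    gene_id = c("n1", "n1"), sample_id = c("m1", "m2"),
    maternal_reads = c(12, 10), paternal_reads = c(4, 0),
    n_snps_observed = 2L, neoX_reads = c(12, NA), neoY_reads = c(4, NA)))
  ann <- toy_annotation()
  sheet <- sample_sheet(data.frame(
    sample_id = c("m1", "m2"), species = "mir_like", stage = 5L, sex = "male",
    replicate = 1:2))
  part <- partition_neo_alleles(al, ann, sheet)
  expect_equal(part$neoX_level[part$sample_id == "m1"], 0.75)
  expect_equal(part$neoY_level[part$sample_id == "m1"], 0.25)
  # genes without neo-divergence SNPs keep combined totals, no partition
  expect_true(is.na(part$neoX_level[part$sample_id == "m2"]))
  expect_equal(part$combined_reads[part$sample_id == "m2"], 10)
})

test_that("zero neo-Y retention makes male neo expression equal the neo-X share", {
  cfg <- small_config("mir_like", seed = 71)
  cfg$neoY_retention_shape1 <- 1e-4   # retention ~ 0
  sim <- simulate_experiment(cfg)
  part <- partition_neo_alleles(sim$allele, sim$ann, sim$sheet)
  part <- part[!is.na(part$neoY_level) & part$combined_reads > 20, ]
  expect_lt(mean(part$neoY_level), 0.02)
})

test_that("ORF strata are indistinguishable when compensation ignores ORF status", {
  sim <- sim_mir()
  norm <- normalize_autosomal(sim$expr, sim$ann)
  fr <- allele_fractions(sim$allele)
  calls <- call_allele_specific(norm, fr, sim$sheet)
  bias <- do.call(rbind, lapply(5:8, function(st)
    fm_ratio(norm, sim$sheet, st, zygotic_calls = calls)))
  class(bias) <- c("bias_table", "data.frame")
  orf <- orf_stratified_bias(bias, sim$ann, mode = "combined_neoXY")
  ps <- orf$tests$p_intact_vs_broken
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 2)
  # retention is drawn independently of ORF status in the generator, so no
  # stage should show a strong stratum difference
  expect_gt(min(ps), 0.001)
  expect_true(all(c("intact", "broken") %in% orf$summary$stratum))
})

test_that("retained neo-Y transcription pushes combined neo-XY ratios toward 1", {
  cfg <- small_config("mir_like", seed = 72)
  cfg$neoY_retention_shape2 <- 1e-4   # retention ~ 1 for every gene
  cfg$compensation_trajectory <- rep(1, 8)
  sim <- simulate_experiment(cfg)
  norm <- normalize_autosomal(sim$expr, sim$ann)
  b <- fm_ratio(norm, sim$sheet, 8)
  b$chrom <- sim$ann$chromosome[match(b$gene_id, sim$ann$gene_id)]
  tg <- sim$truth$genes
  zyg <- tg$gene_id[tg$is_zygotic & !tg$is_maternal & tg$onset_stage <= 6]
  neo <- b$included & b$chrom == "Chr3_neoXY" & b$gene_id %in% zyg
  x <- b$included & b$chrom %in% c("XL", "XR") & b$gene_id %in% zyg
  expect_equal(mean(b$ratio[neo]), 1, tolerance = 0.1)
  expect_equal(mean(b$ratio[x]), 2, tolerance = 0.15)
})
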