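test_that("nearest-neighbour distances match their definition and an all-pairs oracle", {
  expect_equal(nn_distance_stat(c(0, 10, 25)), mean(c(10, 10, 15)))
  expect_equal(nn_distance_stat(c(100, 40)), 60)
  expect_error(nn_distance_stat(5), "at least 2")
  # brute-force all-pairs oracle on random sets
  set.seed(5)
  for (i in 1:20) {
    pos <- sample.int(1e6, 50)
    oracle <- mean(vapply(seq_along(pos), function(j) {
      min(abs(pos[j] - pos[-j]))
    }, numeric(1)))
    expect_equal(nn_distance_stat(pos), oracle)
  }
})

test_that("nearest-neighbour stat is translation- and scale-equivariant", {
  set.seed(6)
  pos <- runif(30, 0, 1e5)
  expect_equal(nn_distance_stat(pos + 12345), nn_distance_stat(pos))
  expect_equal(nn_distance_stat(pos * 3), 3 * nn_distance_stat(pos))
})

test_that("clustering test p-values are uniform under random labels", {
  set.seed(8)
  universe <- runif(200, 0, 1e6)
  ps <- vapply(1:400, function(i) {
    labelled <- sample(universe, 30)
    nn_clustering_test(labelled, universe, n_reps = 199)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # the add-one convention bounds p away from 0 and at 1
  expect_true(all(ps >= 1 / 200 & ps <= 1))
})

test_that("a contiguous block of genes is maximally clustered", {
  set.seed(9)
  universe <- sort(runif(300, 0, 3e6))
  block <- universe[101:130]   # contiguous stretch
  r <- nn_clustering_test(block, universe, n_reps = 499, seed = 2)
  expect_lte(r$p_value, 1 / 100)
  expect_error(nn_clustering_test(universe, block), "larger than")
})

test_that("zygotic-gene clustering is detected against the all-gene null only", {
  cfg <- small_config("pse_like", seed = 81)
  cfg$cluster_zygotic <- TRUE
  sim <- simulate_experiment(cfg)
  tg <- sim$truth$genes
  chr2 <- sim$ann[sim$ann$chromosome == "Chr2", ]
  zyg <- intersect(chr2$gene_id, tg$gene_id[tg$is_zygotic])
  pos <- stats::setNames(chr2$start, chr2$gene_id)
  # zygotic genes clustered relative to all genes...
  r_all <- nn_clustering_test(pos[zyg], pos, n_reps = 999, seed = 3)
  expect_lt(r_all$p_value, 0.05)
  # ...but a random subset of zygotic genes is not clustered within them
  set.seed(4)
  sub <- sample(zyg, 20)
  r_zyg <- nn_clustering_test(pos[sub], pos[zyg], n_reps = 999, seed = 5)
  expect_gt(r_zyg$p_value, 0.05)
})

test_that("clustering_test drives the per-stage, per-label machinery", {
  sim <- sim_pse()
  norm <- normalize_autosomal(sim$expr, sim$ann)
  calls <- call_transcript_level(norm, sim$sheet)
  bias <- fm_ratio(norm, sim$sheet, 8, zygotic_calls = calls)
  labels <- compensation_labels(bias, threshold = 1.5)
  res <- clustering_test(labels, sim$ann,
                         zygotic_genes = rownames(norm$values)[calls$zygotic],
                         null_universe = "zygotic", n_reps = 199, seed = 6)
  expect_true(all(res$p_value >= 1 / 200 & res$p_value <= 1))
  expect_true(all(res$label %in% c("compensated", "uncompensated")))
})

test_that("distance to high-affinity sites is zero inside and quartiles split 2:6", {
  ann <- gene_annotation(data.frame(
    gene_id = sprintf("x%d", 1:8), chromosome = "XL",
    start = c(50L, 150L, 300L, 500L, 800L, 1200L, 1700L, 2300L),
    end = c(60L, 160L, 310L, 510L, 810L, 1210L, 1710L, 2310L)))
  has <- data.frame(chromosome = "XL", start = 40L, end = 70L)
  bias <- structure(data.frame(
    gene_id = ann$gene_id, stage = 5L, female_mean = 20, male_mean = 10,
    ratio = c(1, 1.2, 2, 2, 2, 2, 2, 2), included = TRUE),
    class = c("bias_table", "data.frame"))
  res <- has_proximity_test(bias, has, ann, min_genes = 8)
  expect_equal(res$n, 8)
  expect_equal(res$n_near, 2)       # lower quartile of 8 genes
  expect_equal(res$mean_ratio_near, 1.1)  # x1 sits inside the site: distance 0
  expect_true(res$p_value < 0.2)
})

test_that("high-affinity-site proximity p-values are uniform when unrelated", {
  sim <- sim_pse()
  norm <- normalize_autosomal(sim$expr, sim$ann)
  bias <- fm_ratio(norm, sim$sheet, 8)
  # random sites and independently shuffled ratios: distance carries no
  # information, so each replicate is an independent draw from the null
  set.seed(10)
  ps <- vapply(1:200, function(i) {
    has <- data.frame(chromosome = c("XL", "XR"),
                      start = as.integer(runif(2, 0, 1e6)))
    has$end <- has$start + 500L
    b <- bias
    b$ratio <- sample(b$ratio)
    has_proximity_test(b, has, sim$ann)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("H4K16ac comparison flags enrichment differences in both directions", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:200)
  labels <- data.frame(
    gene_id = rep(genes, 2), stage = rep(c(3L, 8L), each = 200),
    ratio = 1, label = rep(c("compensated", "uncompensated"), 200))
  # late stage: compensated genes carry high enrichment; early stage: low
  enrichment <- stats::setNames(runif(200, 0.4, 0.6), genes)
  comp <- labels$label == "compensated"
  enrichment_late <- enrichment
  res_neutral <- h4k16ac_compare(labels[labels$stage == 3, ], enrichment,
                                 n_boot = 500, seed = 1)
  expect_true(all(res_neutral$compensated_outside == "no"))
  e2 <- enrichment
  e2[genes %in% labels$gene_id[comp]] <- runif(sum(comp) / 2, 0.75, 0.85)
  res_hi <- h4k16ac_compare(labels[labels$stage == 8, ], e2,
                            n_boot = 500, seed = 2)
  expect_equal(res_hi$compensated_outside, "above")
  expect_equal(res_hi$uncompensated_outside, "below")
  e3 <- enrichment
  e3[genes %in% labels$gene_id[comp]] <- runif(sum(comp) / 2, 0.15, 0.25)
  res_lo <- h4k16ac_compare(labels[labels$stage == 3, ], e3,
                            n_boot = 500, seed = 3)
  expect_equal(res_lo$compensated_outside, "below")
})
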