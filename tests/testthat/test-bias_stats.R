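make_bias_expr <- function(f_vals, m_vals, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_along(f_vals))
  m <- cbind(f1 = f_vals, f2 = f_vals, m1 = m_vals, m2 = m_vals)
  rownames(m) <- genes
  sheet <- sample_sheet(data.frame(
    sample_id = c("f1", "f2", "m1", "m2"), species = "pse_like", stage = 5L,
    sex = c("female", "female", "male", "male"), replicate = c(1:2, 1:2)))
  list(expr = expression_table(m), sheet = sheet)
}

test_that("female:male ratios honour the two-sex inclusion rule", {
  inp <- make_bias_expr(c(20, 6, 20), c(10, 4, 3))
  b <- fm_ratio(inp$expr, inp$sheet, stage = 5)
  expect_equal(b$ratio[1], 2.0)
  expect_false(b$included[2])                 # male mean 4 < 5 RPKM
  expect_false(b$included[3])                 # male mean 3 < 5 RPKM
  expect_true(is.na(b$ratio[3]))
  # a stage missing one sex is skipped with a warning
  sheet_f <- inp$sheet[inp$sheet$sex == "female", ]
  class(sheet_f) <- c("sample_sheet", "data.frame")
  expect_warning(out <- fm_ratio(inp$expr, sheet_f, stage = 5), "lacks")
  expect_equal(nrow(out), 0L)
})

test_that("ratios scale inversely with a male-wide multiplier", {
  inp <- make_bias_expr(c(20, 30, 40), c(10, 10, 10))
  b1 <- fm_ratio(inp$expr, inp$sheet, stage = 5)
  e2 <- inp$expr
  e2$values[, c("m1", "m2")] <- e2$values[, c("m1", "m2")] * 2
  b2 <- fm_ratio(e2, inp$sheet, stage = 5)
  expect_equal(b2$ratio, b1$ratio / 2)
})

test_that("bias classes partition the ratio axis at the fixed cut points", {
  r <- c(2.5, 1.75, 1.4, 1.0, 0.5)
  cl <- bias_class(r)
  expect_equal(as.character(cl),
               c("female_gt2", "female_1.5_2", "female_1.25_1.5",
                 "unbiased", "male_biased"))
  # proportions per chromosome sum to one
  inp <- make_bias_expr(c(30, 20, 12, 40), c(10, 19, 11, 30),
                        genes = c("a1", "a2", "x1", "x2"))
  b <- fm_ratio(inp$expr, inp$sheet, stage = 5)
  cb <- classify_bias(b, toy_annotation())
  sums <- tapply(cb$proportion, paste(cb$chromosome, cb$stage), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("chi-squared cutoff comparison matches the hand-computed statistic", {
  # 30/100 vs 50/100 above the cutoff
  a <- c(rep(2, 30), rep(1, 70))
  b <- c(rep(2, 50), rep(1, 50))
  res <- chisq_cutoff_compare(a, b, cutoff = 1.5)
  # independent oracle: sum (obs - exp)^2 / exp over the 2x2 table
  tab <- rbind(c(30, 70), c(50, 50))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2_oracle <- sum((tab - expected)^2 / expected)
  expect_equal(res$statistic, chi2_oracle, tolerance = 1e-12)
  expect_equal(res$statistic, 8.3333333, tolerance = 1e-6)
  # p-value against the closed-form chi-square(1) tail: 2 * pnorm(-sqrt(x))
  expect_equal(res$p_value, 2 * pnorm(-sqrt(chi2_oracle)), tolerance = 1e-10)
  # symmetry in group order
  res_rev <- chisq_cutoff_compare(b, a, cutoff = 1.5)
  expect_equal(res_rev$statistic, res$statistic)
  # identical proportions give a null result
  res0 <- chisq_cutoff_compare(a, a, cutoff = 1.5)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("the cutoff scan reports the grid with BH adjustment", {
  set.seed(1)
  mk <- function(r) {
    structure(data.frame(gene_id = sprintf("g%d", seq_along(r)), stage = 5L,
                         female_mean = 10 * r, male_mean = 10, ratio = r,
                         included = TRUE),
              class = c("bias_table", "data.frame"))
  }
  scan <- chisq_cutoff_scan(mk(runif(200, 1, 2.5)), mk(runif(200, 1, 2.5)))
  expect_equal(scan$cutoff, seq(1.5, 2, by = 0.1))
  expect_true(all(scan$p_adjust_bh >= scan$p_value - 1e-15))
})

test_that("Wilcoxon comparison matches exact enumeration on small samples", {
  res <- wilcoxon_compare(c(1, 2, 3), c(4, 5, 6))
  # independent oracle: enumerate all assignments of ranks 1..6 to group A
  pooled <- 1:6
  w_obs <- sum(rank(pooled)[1:3]) - 3 * 4 / 2       # Mann-Whitney U for A
  combos <- combn(6, 3)
  u <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]) - 6)
  p_exact <- mean(abs(u - 4.5) >= abs(w_obs - 4.5))
  expect_equal(res$p_value, p_exact)
  expect_equal(res$p_value, 0.1)
  expect_true(res$exact)
})

test_that("Wilcoxon approximation tracks enumeration closely at n = 10", {
  set.seed(7)
  diffs <- vapply(1:20, function(i) {
    a <- sample(seq(0.01, 1, by = 0.01), 10)
    b <- sample(setdiff(seq(0.01, 2, by = 0.01), a), 10)
    exact <- wilcoxon_compare(a, b)               # n <= 10, no ties: exact
    stopifnot(exact$exact)
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
    abs(exact$p_value - min(1, approx))
  }, numeric(1))
  expect_lt(mean(diffs), 0.01)
})

test_that("identical groups give p = 1", {
  expect_equal(wilcoxon_compare(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_equal(wilcoxon_compare(c(1, 3, 5), c(5, 1, 3))$p_value, 1)
})

test_that("Wilcoxon type-I error is near nominal under the null", {
  set.seed(11)
  n_sim <- 10000
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    a <- rnorm(20); b <- rnorm(20)
    rej[i] <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value) < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("stage correspondence recovers matched stages", {
  # split one experiment's replicate embryos into two pseudo-datasets that
  # share the same gene programs, emulating two conserved timecourses
  sim <- sim_pse()
  sub <- function(reps) {
    keep <- sim$sheet$replicate %in% reps
    sheet <- sim$sheet[keep, ]
    class(sheet) <- c("sample_sheet", "data.frame")
    list(expr = expression_table(sim$expr$values[, sheet$sample_id]),
         sheet = sheet)
  }
  a <- sub(1L); b <- sub(2:3)
  sc <- stage_correspondence(a$expr, b$expr, a$sheet, b$sheet,
                             n_boot = 100, seed = 5)
  # the diagonal is the row maximum for nearly all stages
  diag_is_max <- vapply(seq_len(8), function(i) {
    which.max(sc$correlation[i, ]) == i
  }, logical(1))
  expect_gte(sum(diag_is_max), 7)
  # bootstrap CIs bracket the observed diagonal correlation
  for (st in c(1, 5, 8)) {
    d <- sc$diagonal[[st]]
    expect_true(d$ci_low <= d$point_estimate + 1e-6 &&
                  d$point_estimate - 1e-6 <= d$ci_high)
  }
})

test_that("stage correspondence is exact on identical and rank-reversed data", {
  set.seed(3)
  n <- 60
  m <- matrix(rlnorm(n * 8, 2, 1), n, 8,
              dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:8)))
  sheet <- sample_sheet(data.frame(
    sample_id = colnames(m), species = "pse_like", stage = 1:8,
    sex = "female", replicate = 1L))
  ea <- expression_table(m)
  sc_same <- stage_correspondence(ea, ea, sheet, sheet, n_boot = 50, seed = 1)
  expect_equal(unname(diag(sc_same$correlation)), rep(1, 8))
  # reversing ranks flips every same-stage correlation to -1
  mr <- max(m) - m
  dimnames(mr) <- dimnames(m)
  sc_rev <- stage_correspondence(ea, expression_table(mr), sheet, sheet,
                                 n_boot = 50, seed = 1)
  expect_equal(unname(diag(sc_rev$correlation)), rep(-1, 8))
})
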