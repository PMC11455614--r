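test_that("build_pseudocells partitions strata and conserves counts", {
  # 90 nuclei in one stratum at target 30 gives 3 pseudocells of 30
  set.seed(1)
  counts <- matrix(rpois(50 * 90, 2), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50), NULL))
  meta <- data.frame(cell_type = "A", sample_id = "s1", condition = "T3",
                     pct_mt = runif(90, 1, 5), stringsAsFactors = FALSE)
  nuc <- nucleus_counts(counts, meta)
  pc <- build_pseudocells(nuc, "A", min_pseudocells = 1, seed = 5)
  expect_false(pc$excluded)
  expect_equal(ncol(pc$counts), 3)
  expect_equal(pc$meta$n_member_nuclei, rep(30L, 3))
  # conservation, per gene and in total
  expect_equal(rowSums(pc$counts), rowSums(counts))
  expect_equal(colSums(pc$counts),
               vapply(pc$membership,
                      function(g) sum(counts[, g]), 0),
               ignore_attr = TRUE)
})

test_that("exclusion rules follow the minimum nuclei / pseudocell counts", {
  set.seed(2)
  mk <- function(n) {
    counts <- matrix(rpois(20 * n, 1), nrow = 20)
    meta <- data.frame(cell_type = "A", sample_id = "s1",
                       condition = "control", pct_mt = 2,
                       stringsAsFactors = FALSE)[rep(1, n), ]
    nucleus_counts(counts, meta)
  }
  # 14 nuclei total: excluded outright
  expect_true(build_pseudocells(mk(14), "A")$excluded)
  # 150 nuclei = 5 pseudocells < 6: excluded
  pc5 <- build_pseudocells(mk(150), "A")
  expect_true(pc5$excluded)
  expect_match(pc5$reason, "5 pseudocells")
  # 180 nuclei = 6 pseudocells: kept
  expect_false(build_pseudocells(mk(180), "A")$excluded)
  # strata under 15 nuclei are dropped silently from the partition
})

test_that("pseudocell metadata uses count-weighted pct_mt", {
  counts <- matrix(c(10, 0, 0, 30), nrow = 1)  # nucleus totals 10,0,0,30
  counts <- rbind(counts, 0)
  rownames(counts) <- c("g1", "g2")
  meta <- data.frame(cell_type = "A", sample_id = "s1", condition = "T3",
                     pct_mt = c(1, 2, 3, 5), stringsAsFactors = FALSE)
  nuc <- nucleus_counts(counts, meta)
  pc <- build_pseudocells(nuc, "A", target_size = 4, min_nuclei = 4,
                          min_pseudocells = 1, seed = 1)
  expect_equal(pc$meta$pct_mt, (10 * 1 + 30 * 5) / 40)
})

test_that("background_genes applies a strict detection threshold", {
  counts <- matrix(0, nrow = 3, ncol = 100,
                   dimnames = list(c("one", "two", "none"), NULL))
  counts["one", 1] <- 5       # 1 of 100 cells: excluded (strict)
  counts["two", 1:2] <- 1     # 2 of 100: included
  meta <- data.frame(cell_type = "A", sample_id = "s1", condition = "T3",
                     pct_mt = 1, stringsAsFactors = FALSE)[rep(1, 100), ]
  nuc <- nucleus_counts(counts, meta)
  expect_equal(background_genes(nuc, "A"), "two")
  expect_equal(background_genes(nuc, "missing"), character(0))
})

test_that("normalize_cp100k matches its definition", {
  m <- matrix(c(10, 90, 0, 50), nrow = 2,
              dimnames = list(c("a", "b"), NULL))
  y <- normalize_cp100k(m)
  expect_equal(unname(y["a", 1]), log2(10 / 100 * 1e5 + 1))
  expect_equal(unname(y["b", 2]), log2(50 / 50 * 1e5 + 1))
})

test_that("with shrinkage disabled the moderated t equals per-gene lm t", {
  nuc <- tiny_nuclei()
  pc <- build_pseudocells(nuc, "typeA", target_size = 10, min_nuclei = 8,
                          min_pseudocells = 4, seed = 3)
  de <- suppressMessages(
    moderated_t_de(pc, d0 = 0, block_method = "none"))
  y <- normalize_cp100k(pc$counts)[de$gene, ]
  covars <- data.frame(pct_mt = pc$meta$pct_mt,
                       log2_n_genes = log2(pc$meta$n_genes))
  cond <- as.numeric(factor(pc$meta$condition,
                            c("control", "T3"))) - 1
  t_or <- oracle_lm_t(y, cond, covars)
  expect_equal(de$t_mod, unname(t_or), tolerance = 1e-9)
  expect_equal(attr(de, "d0"), 0)
})

test_that("log2 fold-changes agree with an independent linear-model fit (limma)", {
  nuc <- tiny_nuclei(seed = 7)
  pc <- build_pseudocells(nuc, "typeA", target_size = 10, min_nuclei = 8,
                          min_pseudocells = 4, seed = 3)
  de <- suppressMessages(moderated_t_de(pc, block_method = "none"))
  y <- normalize_cp100k(pc$counts)[de$gene, ]
  design <- model.matrix(~ cond + pct_mt + lg,
                         data.frame(cond = factor(pc$meta$condition,
                                                  c("control", "T3")),
                                    pct_mt = pc$meta$pct_mt,
                                    lg = log2(pc$meta$n_genes)))
  fit <- limma::lmFit(y, design)
  expect_equal(de$log2fc, unname(fit$coefficients[, "condT3"]),
               tolerance = 1e-9)
})

test_that("constant covariates are dropped without touching the contrast", {
  nuc <- tiny_nuclei(seed = 11)
  nuc$meta$pct_mt <- 2.5  # constant
  pc <- build_pseudocells(nuc, "typeA", target_size = 10, min_nuclei = 8,
                          min_pseudocells = 4, seed = 3)
  expect_message(
    de <- moderated_t_de(pc, d0 = 0, block_method = "none"),
    "constant")
  de2 <- suppressMessages(
    moderated_t_de(pc, d0 = 0, covariates = "log2_n_genes",
                   block_method = "none"))
  expect_equal(de$log2fc, de2$log2fc)
})

test_that("BH adjustment equals the step-up oracle", {
  set.seed(9)
  for (i in 1:5) {
    p <- runif(200)^2
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
  }
})

test_that("rob_scores counts cross-condition pairs with sign semantics", {
  cond <- rep(c("T3", "control"), each = 4)
  # all 16 pairs up
  m1 <- matrix(c(rep(2, 4), rep(1, 4)), nrow = 1)
  expect_equal(unname(rob_scores(m1, cond)), 1)
  # 12 of 16 up, 4 down: exactly the 0.5 threshold (75% concordance)
  m2 <- matrix(c(3, 3, 3, 1, 2, 2, 2, 2), nrow = 1)  # t3: 3,3,3,1; c: 2,2,2,2
  expect_equal(unname(rob_scores(m2, cond)), (12 - 4) / 16)
  # 8 up 8 down
  m3 <- matrix(c(3, 3, 1, 1, 2, 2, 2, 2), nrow = 1)
  expect_equal(unname(rob_scores(m3, cond)), 0)
  # ties contribute zero
  m4 <- matrix(rep(1, 8), nrow = 1)
  expect_equal(unname(rob_scores(m4, cond)), 0)
  # antisymmetry under condition swap
  set.seed(4)
  m5 <- matrix(rnorm(80), nrow = 10)
  swapped <- ifelse(cond == "T3", "control", "T3")
  expect_equal(rob_scores(m5, cond), -rob_scores(m5, swapped))
  expect_error(rob_scores(m5, rep("T3", 8)), "both conditions")
})

test_that("call_trgs applies the joint FDR and robustness criteria", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   mean_expr = c(5, 4, 3, 2),
                   log2fc = c(1, 1, 1, 0),
                   t_mod = c(5, 5, 1, 0),
                   p = c(1e-4, 1e-4, 0.3, 0.9),
                   fdr = c(0.01, 0.01, 0.2, 0.9),
                   stringsAsFactors = FALSE)
  rob <- c(a = 0.6, b = 0.4, c = 1.0, d = 0)
  pct <- c(a = 0.5, b = 0.2, c = 0.9, d = 0)
  out <- call_trgs(de, rob, pct)
  expect_equal(out$is_trg, c(TRUE, FALSE, FALSE, FALSE))
  # non-TRGs: fdr > 0.05 and both robScores exactly 0, among top expressed
  expect_equal(attr(out, "non_trgs"), "d")
})

test_that("the null pipeline calls ~no TRGs and spikes are recovered", {
  # reduced scale for routine testing; the acceptance suite runs the full
  # 4v4 x 5000-gene design
  g <- gen_counts(counts_spec(n_genes = 1200, nuclei_per_sample = 150,
                              seed = 21))
  de <- pseudocell_de_pipeline(g$nuclei, "L2.3.IT", seed = 2)
  spiked <- intersect(g$truth$gene[g$truth$spiked], de$gene)
  recall <- mean(spiked %in% de$gene[de$is_trg])
  expect_gt(recall, 0.7)
  g0 <- gen_counts(counts_spec(n_genes = 1200, nuclei_per_sample = 150,
                               spike_fraction = 0, seed = 22))
  de0 <- pseudocell_de_pipeline(g0$nuclei, "L2.3.IT", seed = 2)
  expect_lt(sum(de0$is_trg), 3)
})

test_that("trg_correlation matches rank and Ward oracles", {
  set.seed(8)
  base <- matrix(rnorm(30 * 4), nrow = 30,
                 dimnames = list(sprintf("g%02d", 1:30),
                                 c("ct1", "ct2", "ct3", "ct4")))
  base[, 2] <- base[, 1] + rnorm(30, 0, 0.3)
  res <- trg_correlation(base)
  # Spearman via independent rank-then-correlate
  for (i in 1:4) for (j in 1:4) {
    expect_equal(res$cor[i, j], oracle_spearman(base[, i], base[, j]),
                 tolerance = 1e-12)
  }
  # ward.D2 merge heights from brute-force agglomeration
  expect_equal(sort(res$hclust$height), oracle_ward_heights(res$cor),
               tolerance = 1e-10)
  # identical vectors correlate at 1; anti-monotone at -1
  two <- cbind(a = base[, 1], b = base[, 1])
  suppressMessages(expect_equal(unname(trg_correlation(
    cbind(two, c = -base[, 1]))$cor["a", "c"]), -1))
  # zero-coverage cell types are excluded with a message
  nacol <- cbind(base, empty = NA_real_)
  expect_message(res2 <- trg_correlation(nacol), "coverage")
  expect_equal(colnames(res2$cor), colnames(base))
})

test_that("disruption_regression recovers constructed signatures", {
  genes <- sprintf("g%02d", 1:40)
  orig <- setNames(rnorm(40, 0, 1), genes)
  # full program reversal
  rev <- disruption_regression(orig, -orig)
  expect_equal(rev$slope, -1, tolerance = 1e-12)
  expect_equal(rev$r_squared, 1, tolerance = 1e-12)
  # independent noise: slope and R2 near zero
  set.seed(10)
  noise <- setNames(rnorm(40, 0, 0.1), genes)
  nl <- disruption_regression(orig, noise)
  expect_lt(abs(nl$slope), 0.15)
  expect_lt(nl$r_squared, 0.2)
  # disrupted set: FDR < 0.05 AND >= 25% fractional change
  delta <- setNames(c(log2(1.3), log2(1.2), 0.9), c("a", "b", "c"))
  orig3 <- setNames(c(1, 1, 1), c("a", "b", "c"))
  fdr <- setNames(c(0.01, 0.01, 0.5), c("a", "b", "c"))
  dr <- disruption_regression(orig3, delta, fdr)
  expect_equal(dr$disrupted, "a")  # b fails the 25% bound, c fails FDR
  expect_error(disruption_regression(orig3[1:2], delta[1:2]), "3 aligned")
})

test_that("MTX round-trip preserves counts and metadata", {
  nuc <- tiny_nuclei(n_genes = 25, nuclei_per_sample = 20, seed = 13)
  dir <- withr::local_tempdir()
  write_nucleus_counts(nuc, dir)
  back <- read_nucleus_counts(file.path(dir, "matrix.mtx"),
                              file.path(dir, "genes.tsv"),
                              file.path(dir, "meta.tsv"))
  expect_equal(as.matrix(back$counts), as.matrix(nuc$counts))
  expect_equal(back$meta$sample_id, nuc$meta$sample_id)
  expect_equal(back$meta$pct_mt, nuc$meta$pct_mt, tolerance = 1e-9)
})
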