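test_that("quantile normalisation matches the sorted-row-means definition", {
  x <- matrix(c(2, 4, 6, 8), ncol = 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  qn <- quantile_normalize(x)
  expect_equal(unname(qn), matrix(c(4, 6, 4, 6), ncol = 2))

  # identical columns are a fixed point
  y <- matrix(c(1, 5, 3, 1, 5, 3), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  expect_equal(quantile_normalize(y), y)

  expect_error(quantile_normalize(y[, 1, drop = FALSE]), ">= 2 samples")

  # rank order preserved within each column; output columns share one multiset
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(rnorm(40), ncol = 4,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
    q <- quantile_normalize(m)
    for (j in 1:4) {
      expect_equal(order(q[, j]), order(m[, j]))
      expect_equal(unname(sort(q[, j])), unname(sort(q[, 1])))
    }
  }
})

test_that("SAM d statistics reproduce hand-computed values", {
  # unpaired: group1 = (1,2), group2 = (3,4), s0 = 0 -> d = 2 / sqrt(0.5)
  x <- matrix(c(1, 2, 3, 4), nrow = 1, dimnames = list("g1", paste0("s", 1:4)))
  d <- sam_statistic(x, sam_design(group = factor(c("a", "a", "b", "b"))),
                     sam_params("two_class_unpaired", s0 = "zero"))
  expect_equal(as.numeric(d), 2 / sqrt(0.5), tolerance = 1e-10)
  expect_equal(as.numeric(d), 2.8284, tolerance = 1e-4)

  # paired: differences (1,2,3), s0 = 0 -> d = 2 / 0.57735
  xp <- matrix(c(0, 1, 0, 2, 0, 3), nrow = 1, dimnames = list("g1", paste0("s", 1:6)))
  dp <- sam_statistic(xp, sam_design(group = factor(rep(c("a", "b"), 3)),
                                     pair = rep(1:3, each = 2)),
                      sam_params("two_class_paired", s0 = "zero"))
  expect_equal(as.numeric(dp), 2 / sqrt(2 / 6), tolerance = 1e-10)
  expect_equal(as.numeric(dp), 3.4641, tolerance = 1e-4)

  # identical groups give d = 0
  xi <- matrix(rep(c(5, 6), each = 2, times = 2), nrow = 2,
               dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  di <- sam_statistic(xi, sam_design(group = factor(c("a", "a", "b", "b"))),
                      sam_params("two_class_unpaired", s0 = 5))
  expect_equal(as.numeric(di), c(0, 0))

  # antisymmetry under group swap
  set.seed(3)
  xr <- matrix(rnorm(24), nrow = 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  d1 <- sam_statistic(xr, sam_design(group = g),
                      sam_params("two_class_unpaired", s0 = 5))
  d2 <- sam_statistic(xr, sam_design(group = factor(g, levels = c("b", "a"))),
                      sam_params("two_class_unpaired", s0 = 5))
  expect_equal(as.numeric(d1), -as.numeric(d2))

  # guard rails
  expect_error(sam_statistic(x, sam_design(group = factor(c("a", "b", "b", "b"))),
                             sam_params("two_class_unpaired")),
               ">= 2 samples")
  xz <- matrix(c(1, 1, 2, 2), nrow = 1, dimnames = list("g1", paste0("s", 1:4)))
  expect_error(sam_statistic(xz, sam_design(group = factor(c("a", "a", "b", "b"))),
                             sam_params("two_class_unpaired", s0 = "zero")),
               "nonzero s0")
})

test_that("permutation FDR is deterministic and separates a strong signal", {
  sim <- simulate_rip_experiment(sim_config(seed = 9, n_genes = 300, n_targets = 50,
                                            enrichment_fold = 8, noise_sd = 0.1))
  des <- paired_design(sim$expr)
  fold <- fold_enrichment(sim$expr$values, des)
  p <- sam_params("two_class_paired", seed = 4)
  r1 <- permutation_fdr(sim$expr$values, des, p, fold = fold)
  r2 <- permutation_fdr(sim$expr$values, des, p, fold = fold)
  expect_identical(r1, r2)
  expect_true(all(r1$fdr >= 0 & r1$fdr <= 1))
  # hugely enriched targets get ~0 fdr
  expect_lt(max(r1$fdr[r1$gene_id %in% sim$truth$targets]), 0.05)
  # per-gene fdr is monotone in rank
  ord <- order(r1$rank)
  expect_true(all(diff(r1$fdr[ord]) >= 0))
})

test_that("fold enrichment averages per-replicate linear ratios", {
  vals <- log2(rbind(g1 = c(4, 4, 4, 2, 2, 2),        # ratios (2,2,2)
                     g2 = c(2, 8, 18, 2, 4, 6)))      # ratios (1,2,3)
  em <- tiny_rip_matrix(vals)
  f <- fold_enrichment(em, paired_design(em))
  expect_equal(unname(f), c(2, 2))
  fg <- fold_enrichment(em, paired_design(em), method = "geometric")
  expect_equal(unname(fg[1]), 2)
  expect_equal(unname(fg[2]), (1 * 2 * 3)^(1 / 3))

  # noise-free simulation: target folds exactly 2
  sim <- simulate_rip_experiment(sim_config(seed = 2, n_genes = 50, n_targets = 10,
                                            enrichment_fold = 2, noise_sd = 0))
  fsim <- fold_enrichment(sim$expr, paired_design(sim$expr))
  expect_equal(unname(fsim[sim$truth$targets]), rep(2, 10))
  expect_equal(unname(fsim[setdiff(names(fsim), sim$truth$targets)]), rep(1, 40))

  bad <- matrix(c(0, 1), nrow = 1, dimnames = list("g1", c("a", "b")))
  expect_error(fold_enrichment(bad, sam_design(group = factor(c("x", "y"))),
                               log2 = FALSE),
               "zero or negative")
})

test_that("target calling applies the fold >= 1.5 AND fdr < 0.05 rule", {
  sam <- structure(data.frame(gene_id = c("cycB_like", "hit", "edge"),
                              d = c(1, 3, 2), fold = c(1.4, 2.0, 1.5),
                              fdr = c(0.08, 0.001, 0.049), rank = c(3, 1, 2),
                              stringsAsFactors = FALSE),
                   class = c("sam_result", "data.frame"))
  calls <- call_targets(sam)
  expect_false("cycB_like" %in% calls$genes)  # 1.4-fold, FDR < 10%: just misses
  expect_true(all(c("hit", "edge") %in% calls$genes))
  expect_named(calls$report, c("gene_id", "d", "fold", "fdr", "rank",
                               "pass_fold", "pass_fdr", "called"))
  empty <- call_targets(sam[0, ])
  expect_length(empty$genes, 0L)
})

test_that("unchanged rule needs both the fold window and the FDR floor", {
  sam <- data.frame(gene_id = c("a", "b", "c", "d"),
                    d = 0, fold = c(1.05, 1.05, 0.95, 1.2),
                    fdr = c(0.9, 0.3, 0.8, 0.9), rank = 1:4)
  expect_setequal(define_unchanged(sam), c("a", "c"))
})

test_that("expressed set recovers a planted high component with union semantics", {
  # bimodal: half at baseline, half 8-fold (3 log2 units) above
  set.seed(11)
  n <- 200; hi <- paste0("g", 1:100)
  vals <- matrix(rnorm(n * 3, 7, 0.25), nrow = n,
                 dimnames = list(paste0("g", 1:n), paste0("s", 1:3)))
  vals[hi, ] <- vals[hi, ] + 3
  em <- expr_matrix(vals, data.frame(sample_id = paste0("s", 1:3),
                                     role = "input", replicate = 1:3))
  expr <- define_expressed(em)
  expect_gte(mean(hi %in% expr), 0.95)
  expect_lte(mean(setdiff(rownames(vals), hi) %in% expr), 0.05)

  # all genes identical: nothing exceeds the mean
  flat <- expr_matrix(matrix(5, nrow = 10, ncol = 3,
                             dimnames = list(paste0("g", 1:10), paste0("s", 1:3))),
                      data.frame(sample_id = paste0("s", 1:3),
                                 role = "input", replicate = 1:3))
  expect_length(define_expressed(flat), 0L)

  # union over conditions: a gene expressed only in the mutant-t4 condition
  set.seed(12)
  v2 <- matrix(rnorm(100 * 6, 7, 0.25), nrow = 100,
               dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  v2["g1", 4:6] <- 12   # high only in condition 2
  em2 <- expr_matrix(v2, data.frame(sample_id = paste0("s", 1:6),
                                    role = rep(c("wildtype", "mutant"), each = 3),
                                    replicate = rep(1:3, 2),
                                    timepoint = rep(c("t1", "t4"), each = 3)))
  expect_true("g1" %in% define_expressed(em2))
})

test_that("null FDR control and power monotonicity hold over seeds", {
  # realized false-discovery proportion at nominal 5% on label-randomised data
  fdp <- vapply(1:20, function(i) {
    sim <- simulate_rip_experiment(sim_config(seed = 500 + i, n_genes = 400,
                                              n_targets = 0, enrichment_fold = 1))
    des <- paired_design(sim$expr)
    fold <- fold_enrichment(sim$expr$values, des)
    sam <- permutation_fdr(sim$expr$values, des,
                           sam_params("two_class_paired", seed = 1), fold = fold)
    called <- call_targets(sam)$genes
    if (length(called) == 0) 0 else 1   # any call on a null is a false discovery
  }, numeric(1))
  se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 2 * max(se, 0.01))

  # sensitivity never decreases along an enrichment grid (mean over seeds)
  sens <- sapply(c(1.5, 2, 3), function(f) {
    mean(vapply(1:5, function(i) {
      sim <- simulate_rip_experiment(sim_config(seed = 700 + i, n_genes = 300,
                                                n_targets = 60, enrichment_fold = f))
      des <- paired_design(sim$expr)
      fold <- fold_enrichment(sim$expr$values, des)
      sam <- permutation_fdr(sim$expr$values, des,
                             sam_params("two_class_paired", seed = 1), fold = fold)
      mean(sim$truth$targets %in% call_targets(sam)$genes)
    }, numeric(1)))
  })
  expect_true(all(diff(sens) >= -0.02))
})
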