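test_that("two-sided Fisher p-values match hypergeometric enumeration", {
  expect_equal(fisher_two_sided(2, 0, 0, 2)$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_two_sided(1, 1, 1, 1)$p_value, 1, tolerance = 1e-12)
  expect_error(fisher_two_sided(-1, 0, 0, 2), "negative")

  # exhaustive small grid plus random larger tables against the oracle
  for (n in 1:16) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      expect_equal(fisher_two_sided(a, b, cc, d)$p_value,
                   fisher_bruteforce(a, b, cc, d), tolerance = 1e-9,
                   info = paste(a, b, cc, d))
    }
  }
  set.seed(4)
  for (i in 1:300) {
    t4 <- as.vector(rmultinom(1, sample(10:60, 1), prob = runif(4)))
    expect_equal(fisher_two_sided(t4[1], t4[2], t4[3], t4[4])$p_value,
                 fisher_bruteforce(t4[1], t4[2], t4[3], t4[4]), tolerance = 1e-9)
  }
})

test_that("BH and Bonferroni corrections match hand computations", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
  # monotone when inputs sorted ascending
  set.seed(5)
  p <- sort(runif(50))
  expect_true(all(diff(bh_fdr(p)) >= 0))

  expect_equal(bonferroni(0.01, m = 4), 0.04)
  expect_equal(bonferroni(0.5, m = 4), 1)
  expect_equal(bonferroni(numeric(0)), numeric(0))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m must be")
})

test_that("quadrant exclusion drops only the doubly-depleted genes", {
  # monotone increasing pairs, none excluded
  r <- spearman_quadrant_excluded(1:10, (1:10)^2)
  expect_equal(r$rho, 1)
  expect_equal(r$n_excluded, 0L)

  # (0.5, 0.5) excluded; remaining (2,4), (4,2) give rho = -1
  r2 <- spearman_quadrant_excluded(c(0.5, 2, 4), c(0.5, 4, 2))
  expect_equal(r2$rho, -1)
  expect_equal(r2$n_used, 2L)
  expect_equal(r2$n_excluded, 1L)

  # genes sub-threshold in only one experiment are never excluded
  set.seed(6)
  for (i in 1:20) {
    x <- runif(30, 0.2, 3); y <- runif(30, 0.2, 3)
    r3 <- spearman_quadrant_excluded(x, y)
    expect_equal(r3$n_excluded, sum(x < 1 & y < 1))
    # with no gene in the excluded quadrant, equals plain Spearman
    xs <- x + 1; ys <- y + 1
    expect_equal(spearman_quadrant_excluded(xs, ys)$rho,
                 cor(xs, ys, method = "spearman"))
  }
  expect_error(spearman_quadrant_excluded(c(0.5, 0.4), c(0.5, 0.4)), "fewer than 2")
})

test_that("rank-sum comparison reports tie-corrected two-sided p and medians", {
  same <- ranksum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)
  r <- ranksum_compare(c(5, 6), c(1, 2))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$median_a, 5.5)
  expect_error(ranksum_compare(numeric(0), 1), "non-empty")

  # power under a 1-sd shift at n = 100/100
  set.seed(8)
  hits <- vapply(1:30, function(i) {
    ranksum_compare(rnorm(100, 1), rnorm(100))$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("term enrichment filters small sets and controls the null", {
  background <- sprintf("g%03d", 1:300)
  sets <- list(small = background[1:10],        # <= 25 members: excluded
               planted = background[1:40],
               other = background[101:160])
  set.seed(9)
  gene_list <- c(background[1:30], sample(background[161:300], 10))
  res <- enrich_terms(gene_list, sets, background)
  expect_false("small" %in% res$term_id)
  planted <- res[res$term_id == "planted", ]
  expect_equal(planted$direction, "enriched")
  expect_lt(planted$q_value, 0.05)
  expect_true(all(res$q_value >= res$p_value))

  expect_error(enrich_terms(c(gene_list, "not_in_bg"), sets, background),
               "outside the background")
  expect_error(enrich_terms(gene_list, sets, character(0)), "empty background")

  # null lists: false-positive fraction at q < 0.05 stays nominal, and raw
  # p-values are conservative-to-uniform (discrete Fisher p)
  set.seed(10)
  sets200 <- lapply(1:200, function(i) sample(background, 40))
  names(sets200) <- paste0("t", 1:200)
  fp <- vapply(1:10, function(i) {
    gl <- sample(background, 30)
    r <- enrich_terms(gl, sets200, background, min_set_size = 26)
    mean(r$q_value < 0.05)
  }, numeric(1))
  expect_lte(mean(fp), 0.05)
  gl <- sample(background, 30)
  r <- enrich_terms(gl, sets200, background)
  for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(r$p_value < alpha), alpha + 0.08)
  }
})

test_that("RPKM ratios flag undefined and infinite cases", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    rpkm_0to2 = c(10, 0, 7, 0),
                    rpkm_2to4 = c(5, 0, 7, 3))
  r <- ratio_2to4_over_0to2(tab)
  expect_equal(unname(r["a"]), 0.5)
  expect_true(is.na(r["b"]))
  expect_equal(unname(r["c"]), 1)
  expect_true(is.infinite(r["d"]))
  expect_equal(attr(r, "n_undefined"), 1L)
  expect_equal(attr(r, "n_infinite"), 1L)
  expect_error(ratio_2to4_over_0to2(tab[, 1:2]), "missing column")
})

test_that("list overlap combines Venn counts with Fisher association", {
  bg <- sprintf("g%03d", 1:200)
  ov <- compare_lists(bg[1:50], bg[26:75], bg)
  expect_equal(ov$n_overlap, 25L)
  expect_equal(ov$expected, 50 * 50 / 200)
  expect_equal(ov$direction, "enriched")
  expect_lt(ov$p_value, 1e-4)
})
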