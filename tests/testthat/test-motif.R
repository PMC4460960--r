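test_that("IUPAC scanning reports all compatible (overlapping) windows", {
  # the degenerate consensus matches the second NRE Box A context (D = G)
  hits <- scan_motif(transcript_record("hb", "hb", "UUUGUUGUU"), "NNUGUUDNN")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)

  expect_equal(nrow(scan_motif(transcript_record("x", "x", "AAAAAA"), "UGUU")), 0L)

  # overlapping hits are all reported
  hits2 <- scan_motif(transcript_record("u", "u", "UUUAAA"), "UUAA")
  expect_equal(hits2$start, 2L)
  hits3 <- scan_motif(transcript_record("u", "u", "UUUUU"), "UUUU")
  expect_equal(hits3$start, c(1L, 2L))

  # region restriction keeps hits fully inside the region
  tx <- transcript_record("r", "r", "UGUUACGUACUGUUACGUAC",
                          utr5 = c(1, 5), orf = c(6, 15), utr3 = c(16, 20))
  expect_equal(scan_motif(tx, "UGUU", region = "utr5")$start, 1L)
  expect_equal(scan_motif(tx, "UGUU", region = "orf")$start, 11L)
  expect_equal(nrow(scan_motif(tx, "UGUU", region = "utr3")), 0L)

  # track length mismatch
  expect_error(scan_motif(tx, "UGUU", accessibility_track("r", 4, rep(0.5, 3))),
               "length")
})

test_that("transcript scores sum match accessibilities", {
  tx <- transcript_record("t", "t", "AUGUUCCUGUUC")
  p <- rep(0, 12); p[c(2 + 3, 8 + 3)] <- c(0.2, 0.3)  # windows ending at hit ends
  tr <- accessibility_track("t", 4, p)
  expect_equal(transcript_score(tx, "UGUU", tr), 0.5)
  expect_equal(transcript_score(tx, "AAAA", tr), 0)  # no match -> 0

  # constant accessibility c: score = c * hit count
  trc <- accessibility_fallback(tx, 4, "constant", c = 0.4)
  expect_equal(transcript_score(tx, "UGUU", trc),
               0.4 * nrow(scan_motif(tx, "UGUU")))
  tr0 <- accessibility_fallback(tx, 4, "constant", c = 0)
  expect_equal(transcript_score(tx, "UGUU", tr0), 0)

  # gc heuristic: deterministic, in range, lower for GC-rich sequence
  gc_rich <- transcript_record("g", "g", strrep("GC", 50))
  au_rich <- transcript_record("a", "a", strrep("AU", 50))
  t1 <- accessibility_fallback(gc_rich, 4, "gc_heuristic")
  t2 <- accessibility_fallback(gc_rich, 4, "gc_heuristic")
  t3 <- accessibility_fallback(au_rich, 4, "gc_heuristic")
  expect_identical(t1$p, t2$p)
  expect_true(all(t1$p[-(1:3)] < t3$p[-(1:3)]))
  expect_error(accessibility_fallback(tx, 4, "constant", c = 2), "\\[0,1\\]")
})

test_that("AUROC agrees with brute-force pair enumeration, ties included", {
  a <- auroc(c(0.9, 0.8), c(0.7, 0.85))
  expect_equal(a$auroc, 0.75)
  expect_equal(auroc(c(1, 0), c(1, 0))$auroc, 0.5)  # identical distributions
  b <- auroc(c(5, 6), c(1, 2))
  expect_equal(b$auroc, 1)
  expect_equal(b$p_value, 1 / 3)  # exact enumeration of C(4,2) labelings

  set.seed(99)
  for (i in 1:200) {
    np <- sample(1:6, 1); nn <- sample(1:6, 1)
    pos <- sample(0:3, np, replace = TRUE) / 2  # frequent ties
    neg <- sample(0:3, nn, replace = TRUE) / 2
    r <- auroc(pos, neg)
    expect_equal(r$auroc, auroc_bruteforce(pos, neg))
    # complementarity
    expect_equal(r$auroc + auroc(neg, pos)$auroc, 1)
  }

  # large-sample p agrees with the tie-corrected wilcox.test approximation
  set.seed(100)
  pos <- rnorm(40, 0.3); neg <- rnorm(50)
  r <- auroc(pos, neg)
  wt <- wilcox.test(pos, neg, exact = FALSE, correct = FALSE)
  expect_equal(r$p_value, wt$p.value, tolerance = 1e-10)
  expect_equal(r$U, unname(wt$statistic))

  expect_error(auroc(numeric(0), 1), "non-empty")
})

test_that("corpus scoring equals per-transcript scoring for degenerate motifs", {
  sim <- simulate_transcriptome(sim_config(seed = 13, n_genes = 40, n_targets = 20))
  corpus <- motif_corpus(sim$transcripts, sim$tracks)
  for (m in c("UUGUUAU", "NNUGUUDNN", "UGUANAKW", "UGUU")) {
    for (region in c("whole", "utr3", "orf")) {
      sc <- score_transcripts(corpus, m, region)
      direct <- vapply(names(sim$transcripts), function(g) {
        transcript_score(sim$transcripts[[g]], m, sim$tracks[[g]], region)
      }, numeric(1))
      expect_equal(sc, direct, info = paste(m, region))
    }
  }
  # constant track of 1: score equals hit count
  corpus1 <- motif_corpus(sim$transcripts, tracks = NULL)
  sc1 <- score_transcripts(corpus1, "UGUU")
  counts <- vapply(names(sim$transcripts), function(g) {
    nrow(scan_motif(sim$transcripts[[g]], "UGUU"))
  }, numeric(1))
  expect_equal(sc1, counts)
})

test_that("discovery recovers an implanted motif and is a greedy ascent", {
  cfg <- sim_config(seed = 11, n_genes = 120, n_targets = 60)
  sim <- simulate_transcriptome(cfg)
  corpus <- motif_corpus(sim$transcripts, sim$tracks)
  neg <- setdiff(names(sim$transcripts), sim$truth$positives)
  disc <- discover_motif(corpus, sim$truth$positives, neg)
  expect_gte(disc$training_auroc, 0.85)
  expect_true(grepl("UGUU", motif_core(disc$motif)))

  # determinism
  disc2 <- discover_motif(corpus, sim$truth$positives, neg)
  expect_identical(motif_string(disc$motif), motif_string(disc2$motif))

  # never below the seeding 7-mer's training AUROC
  seed_row <- disc$seed_table[disc$seed_table$kmer == disc$seed, ]
  expect_gte(disc$training_auroc, seed_row$auroc)
  expect_true(all(disc$seed_table$refined_auroc >= disc$seed_table$auroc - 1e-12))

  # input validation
  expect_error(discover_motif(corpus, sim$truth$positives,
                              c(neg, sim$truth$positives[1])), "overlap")
  expect_error(discover_motif(corpus, sim$truth$positives[1:5], neg[1:5]),
               "at least")
})

test_that("null data yields chance-level held-out discrimination", {
  cfg <- sim_config(seed = 17, n_genes = 120, n_targets = 60, sites_per_target = 0L)
  sim <- simulate_transcriptome(cfg)
  corpus <- motif_corpus(sim$transcripts, sim$tracks)
  pos <- sim$truth$positives
  neg <- setdiff(names(sim$transcripts), pos)
  # train on half, evaluate on the held-out half
  tr_p <- pos[1:30]; te_p <- pos[31:60]
  tr_n <- neg[1:30]; te_n <- neg[31:60]
  disc <- discover_motif(corpus, tr_p, tr_n)
  sc <- score_transcripts(corpus, disc$motif)
  held <- auroc(sc[te_p], sc[te_n])$auroc
  expect_lt(abs(held - 0.5), 0.15)
})

test_that("cross-validation emits exactly repeats x folds held-out AUROCs", {
  cfg <- sim_config(seed = 19, n_genes = 80, n_targets = 40)
  sim <- simulate_transcriptome(cfg)
  corpus <- motif_corpus(sim$transcripts, sim$tracks)
  neg <- setdiff(names(sim$transcripts), sim$truth$positives)
  cv <- cross_validate(corpus, sim$truth$positives, neg,
                       motif_params(n_seeds = 3, n_repeats = 2, n_folds = 5, seed = 2))
  expect_length(cv$aurocs, 10L)
  expect_equal(cv$mean_auroc, mean(cv$aurocs))
  # strong implanted signal: held-out discrimination is high
  expect_gte(cv$mean_auroc, 0.8)
  # no optimistic leakage: cv mean does not beat full-data training AUROC
  disc <- discover_motif(corpus, sim$truth$positives, neg,
                         motif_params(n_seeds = 3))
  expect_lte(cv$mean_auroc, disc$training_auroc + 0.02)

  expect_error(cross_validate(corpus, sim$truth$positives[1:5], neg,
                              motif_params(n_folds = 10)),
               "fewer bins")
})

test_that("region enrichment localises 3'UTR implants and handles nulls", {
  cfg <- sim_config(seed = 23, n_genes = 80, n_targets = 40)
  sim <- simulate_transcriptome(cfg)
  corpus <- motif_corpus(sim$transcripts, sim$tracks)
  neg <- setdiff(names(sim$transcripts), sim$truth$positives)
  re <- region_enrichment(sim$truth$positives, neg, cfg$motif, corpus)
  utr3 <- re$auroc[re$region == "utr3"]
  expect_gt(utr3, re$auroc[re$region == "orf"])
  expect_gt(utr3, re$auroc[re$region == "utr5"])
  expect_true(all(re$p_bonferroni >= re$p_value))

  # scrambled labels: all regions near chance
  set.seed(1)
  scr <- sample(names(sim$transcripts))
  re0 <- region_enrichment(scr[1:40], scr[41:80], cfg$motif, corpus)
  expect_true(all(abs(re0$auroc - 0.5) < 0.2))

  # motif with no matches anywhere: all scores 0, AUROC 0.5 by tie convention
  re_none <- region_enrichment(sim$truth$positives, neg, "CCCCCCCCC", corpus)
  expect_true(all(re_none$auroc == 0.5))
})

test_that("motif utilities expose core, degeneracy, PWM and compatibility", {
  m <- iupac_motif("NNUGUUDNN")
  expect_equal(m$width, 9L)
  expect_equal(motif_core(m), "UGUU")
  expect_equal(motif_degeneracy(m), 5L)
  pwm <- motif_pwm(m)
  expect_equal(colSums(pwm), rep(1, 9))
  expect_equal(pwm[, 1], c(A = 0.25, C = 0.25, G = 0.25, U = 0.25))
  expect_equal(unname(pwm["U", 3]), 1)

  expect_true(iupac_compatible("UGUUD", "UGUUG"))
  expect_false(iupac_compatible("UGUUD", "UGUUC"))
  expect_error(iupac_motif("UGU"), "width >= 4")
  expect_error(iupac_motif("UGXU"), "IUPAC")
})
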