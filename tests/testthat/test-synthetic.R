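test_that("generators are pure functions of the config", {
  cfg <- sim_config(seed = 21, n_genes = 80, n_targets = 20)
  expect_identical(simulate_rip_experiment(cfg), simulate_rip_experiment(cfg))
  expect_identical(simulate_transcriptome(cfg), simulate_transcriptome(cfg))
  expect_identical(simulate_timecourse(cfg), simulate_timecourse(cfg))
  expect_identical(simulate_rnacompete(sim_config(seed = 21, n_probes = 200)),
                   simulate_rnacompete(sim_config(seed = 21, n_probes = 200)))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_targets = 10, n_genes = 5), "n_targets")
  expect_error(sim_config(enrichment_fold = 0), "enrichment_fold")
  expect_error(sim_config(accessibility_high = 1.2), "\\[0,1\\]")
  expect_error(sim_config(class_proportions = rep(0.2, 6)), "summing")
  expect_error(sim_config(motif = "UUXGU"), "IUPAC")
})

test_that("null RIP design centres log ratios at zero; noise-free is exact", {
  null <- simulate_rip_experiment(sim_config(seed = 3, n_genes = 500, n_targets = 100,
                                             enrichment_fold = 1))
  des <- paired_design(null$expr)
  lf <- log2(fold_enrichment(null$expr, des, method = "geometric"))
  expect_lt(abs(mean(lf)), 0.05)

  exact <- simulate_rip_experiment(sim_config(seed = 3, n_genes = 50, n_targets = 10,
                                              enrichment_fold = 2, noise_sd = 0))
  r <- 2^(exact$expr$values[, 1:3] - exact$expr$values[, 4:6])
  expect_equal(unname(r[exact$truth$targets, ]),
               matrix(2, nrow = 10, ncol = 3))
})

test_that("implants land in 3'UTRs at the configured accessibility", {
  cfg <- sim_config(seed = 31, n_genes = 60, n_targets = 30, sites_per_target = 2,
                    accessibility_high = 1, accessibility_low = 0)
  sim <- simulate_transcriptome(cfg)
  expect_length(sim$truth$implants, 30L)
  expect_true(all(lengths(sim$truth$implants) == 2L))
  w <- nchar(cfg$motif)
  for (g in sim$truth$positives) {
    tx <- sim$transcripts[[g]]
    starts <- sim$truth$implants[[g]]
    expect_true(all(starts >= tx$utr3[1] & starts + w - 1 <= tx$utr3[2]))
    # with accessibility 1 at sites and 0 elsewhere, score = implant count
    sc <- transcript_score(tx, cfg$motif, sim$tracks[[g]])
    expect_equal(sc, 2)
  }
  negs <- setdiff(names(sim$transcripts), sim$truth$positives)
  neg_scores <- vapply(negs, function(g) {
    transcript_score(sim$transcripts[[g]], cfg$motif, sim$tracks[[g]])
  }, numeric(1))
  expect_true(all(neg_scores == 0))
})

test_that("spontaneous 7-mer matches occur at the uniform-sequence rate", {
  # negatives carry no implants: count exact matches of a fixed 7-mer
  cfg <- sim_config(seed = 41, n_genes = 1000, n_targets = 0,
                    utr5_len = 0L, orf_len = 0L, utr3_len = 300L,
                    sites_per_target = 0L)
  sim <- simulate_transcriptome(cfg)
  counts <- vapply(names(sim$transcripts), function(g) {
    nrow(scan_motif(sim$transcripts[[g]], "UUGUUAU"))
  }, numeric(1))
  n_len <- 300
  expected <- (n_len - 6) * 4^-7
  se <- sqrt(expected / length(counts))  # Poisson-scale sampling error
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("timecourse profiles follow their archetype exactly at zero noise", {
  cfg <- sim_config(seed = 5, n_genes = 120, noise_sd = 0,
                    class_proportions = setNames(rep(1 / 6, 6), LETTERS[1:6]))
  sim <- simulate_timecourse(cfg)
  prof <- profile_set(sim$expr, "wildtype")
  z <- t(apply(prof$profiles, 1, function(x) (x - mean(x)) / sd(x)))
  shapes <- t(apply(sim$truth$archetypes, 1, function(x) (x - mean(x)) / sd(x)))
  for (g in rownames(z)) {
    expect_equal(unname(z[g, ]), unname(shapes[sim$truth$class[g], ]),
                 tolerance = 1e-10)
  }

  # stabilization factor 1 (and no secondary effects): mutant equals wild type
  cfg1 <- sim_config(seed = 5, n_genes = 60, noise_sd = 0, stabilization_factor = 1,
                     secondary_up = 0,
                     class_proportions = setNames(rep(1 / 6, 6), LETTERS[1:6]))
  sim1 <- simulate_timecourse(cfg1)
  wt <- profile_set(sim1$expr, "wildtype")$profiles
  mut <- profile_set(sim1$expr, "mutant")$profiles
  expect_equal(mut, wt, tolerance = 1e-10)
})

test_that("probe intensities track the hidden 7-mer occurrence count", {
  cfg <- sim_config(seed = 8, n_probes = 300, rnacompete_noise_sd = 0)
  sim <- simulate_rnacompete(cfg)
  expect_equal(sim$pool$intensity,
               cfg$rnacompete_baseline + cfg$affinity_beta * sim$truth$counts)
  expect_true(all(nchar(sim$pool$sequence) >= 30 & nchar(sim$pool$sequence) <= 41))
})
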