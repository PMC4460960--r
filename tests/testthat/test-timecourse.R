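test_that("Pearson-distance k-means recovers duplicated profile groups", {
  shapes <- rbind(up = c(0, 1, 2, 3), down = c(3, 2, 1, 0))
  x <- shapes[rep(1:2, each = 10), ] + matrix(rnorm(80, 0, 0.01), ncol = 4)
  rownames(x) <- paste0("g", 1:20)
  colnames(x) <- paste0("t", 1:4)
  fit <- kmeans_pearson(x, k = 2, seed = 1)
  expect_equal(length(unique(fit$labels[1:10])), 1L)
  expect_equal(length(unique(fit$labels[11:20])), 1L)
  expect_false(fit$labels[1] == fit$labels[11])

  # determinism
  fit2 <- kmeans_pearson(x, k = 2, seed = 1)
  expect_identical(fit$labels, fit2$labels)

  # Pearson distance is invariant to per-gene affine rescaling
  fit3 <- kmeans_pearson(2 * x + 5, k = 2, seed = 1)
  expect_identical(fit$labels, fit3$labels)

  # profiles proportional to one shape: all in one effective cluster
  prop <- outer(c(1, 2, 5, 9, 0.5), c(0, 1, 2, 3))
  prop <- prop + 1  # affine variants of the same shape
  rownames(prop) <- paste0("p", 1:5); colnames(prop) <- paste0("t", 1:4)
  z <- ripmzt:::.standardize_rows(prop)
  expect_true(all(abs(ripmzt:::.pearson_dist(z, z[1, , drop = FALSE])) < 1e-12))

  expect_error(kmeans_pearson(x[1:3, ], k = 4), "at least k")
})

test_that("consensus clustering reports modal partition frequency", {
  cfg <- sim_config(seed = 33, n_genes = 300, noise_sd = 0.2,
                    class_proportions = setNames(rep(1 / 6, 6), LETTERS[1:6]))
  sim <- simulate_timecourse(cfg)
  prof <- profile_set(sim$expr, "wildtype")
  cc <- consensus_clusters(prof, k = 6, n_restarts = 30, seed = 3)
  expect_gte(cc$modal_frequency, 0.5)
  # each truth class maps to exactly one recovered cluster
  tab <- table(sim$truth$class[names(cc$labels)], cc$labels)
  expect_true(all(apply(tab > 3, 1, sum) == 1))
  ari <- mclust::adjustedRandIndex(cc$labels, sim$truth$class[names(cc$labels)])
  expect_gte(ari, 0.9)

  # pure-noise profiles are unstable: warning when modal frequency < 0.5
  set.seed(13)
  noise <- matrix(rnorm(240), ncol = 4,
                  dimnames = list(paste0("n", 1:60), paste0("t", 1:4)))
  expect_warning(consensus_clusters(noise, k = 6, n_restarts = 20, seed = 1),
                 "unstable")
})

test_that("profile sets average replicates and route constant genes aside", {
  cfg <- sim_config(seed = 35, n_genes = 40, noise_sd = 0)
  sim <- simulate_timecourse(cfg)
  prof <- profile_set(sim$expr, "wildtype")
  g <- rownames(prof$profiles)[1]
  keep <- sim$expr$samples$role == "wildtype" &
    sim$expr$samples$timepoint == "t2"
  expect_equal(unname(prof$profiles[g, "t2"]),
               mean(sim$expr$values[g, keep]))
  # flat-shaped genes at zero noise are constant in wild type, hence
  # unclusterable
  flat <- names(sim$truth$class)[sim$truth$class %in% c("flat", "down")]
  expect_setequal(prof$unclusterable, flat)
})

test_that("figure of merit falls to the planted class count then flattens", {
  cfg <- sim_config(seed = 3, n_genes = 240, noise_sd = 0.25,
                    class_proportions = setNames(rep(1 / 6, 6), LETTERS[1:6]))
  sim <- simulate_timecourse(cfg)
  prof <- profile_set(sim$expr, "wildtype")
  fom <- figure_of_merit(prof, k_range = 1:8, seed = 3)
  expect_equal(nrow(fom), 8L)
  # k = 1: no clustering, FOM equals the adjusted per-timepoint spread
  z <- ripmzt:::.standardize_rows(prof$profiles)
  n <- nrow(z)
  direct <- mean(vapply(1:4, function(tp) {
    v <- z[, tp]
    sqrt(sum((v - mean(v))^2) / n) * sqrt(n / (n - 1))
  }, numeric(1)))
  expect_equal(fom$fom[fom$k == 1], direct, tolerance = 1e-10)
  # the curve declines into the planted k and flattens beyond it
  expect_lt(fom$fom[fom$k == 6], fom$fom[fom$k == 2])
  drop_to_6 <- fom$fom[fom$k == 2] - fom$fom[fom$k == 6]
  drop_after <- fom$fom[fom$k == 6] - min(fom$fom[fom$k > 6])
  expect_lt(drop_after, 0.5 * drop_to_6)

  expect_error(figure_of_merit(prof$profiles[1:5, ], k_range = 2:6), "below the gene count")
})

test_that("archetype rules tag the six canonical shapes and ambiguity", {
  cents <- rbind(c(1.0, 0.4, 0.2, 0.8),    # decline then re-expression
                 c(1.0, 0.7, 0.4, 0.2),    # monotone decline
                 c(0.5, 0.5, 0.1, 0.1),    # flat then decline
                 c(0.2, 1.0, 0.6, 0.4),    # zygotic, max t2
                 c(0.2, 0.6, 1.0, 0.7),    # zygotic, max t3
                 c(0.1, 0.3, 0.7, 1.0))    # zygotic, max t4
  tags <- label_archetypes(cents)
  expect_equal(unname(tags), c("A-like", "B-like", "C-like",
                               "D-like", "E-like", "F-like"))
  # a late riser without early decline sits between families: mixed
  expect_equal(unname(label_archetypes(rbind(c(0.5, 0.5, 0.5, 1.0),
                                             c(1, 0.4, 0.2, 0.8)))[1]),
               "mixed")
  expect_error(label_archetypes(cents[, 1:3]), "4 timepoints")
})
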