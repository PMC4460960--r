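## Seeded synthetic-data generators with ground truth: paired RIP/control
## arrays, transcriptomes with implanted accessible motif sites, a
## two-genotype four-timepoint decay course, and RNAcompete-style probe
## pools. All generators are pure functions of the config (seed included).

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data module with validated
#' defaults. The defaults are the package's standard study conditions:
#' three-replicate paired RIP/control arrays with a 2-fold planted
#' enrichment, log2-additive Gaussian noise (sd 0.25), a UUGUUAU implant
#' at high-accessibility 3'UTR sites (0.9 vs background 0.1), four
#' timepoints with six dynamic classes and 3-fold mutant stabilisation of
#' the maternal-decay classes, and a 2,000-probe 30-41 nt pool with a
#' hidden affinity 7-mer.
#'
#' @param seed integer RNG seed; each generator derives its stream from it
#'   by a fixed documented offset.
#' @param n_genes,n_targets gene universe size and planted target count.
#' @param n_replicates paired replicates (default 3).
#' @param enrichment_fold linear RIP/control factor for targets.
#' @param noise_sd log2-scale Gaussian noise sd.
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution.
#' @param motif IUPAC string implanted into positive 3'UTRs.
#' @param sites_per_target implanted sites per positive transcript.
#' @param accessibility_high,accessibility_low unpaired probability at
#'   implanted site windows vs background.
#' @param utr5_len,orf_len,utr3_len region lengths of simulated
#'   transcripts (nt).
#' @param class_proportions named length-6 vector of class fractions
#'   (A-F), summing to at most 1; the remainder are flat/unchanged genes.
#' @param timecourse_amplitude log2 amplitude of the class archetypes.
#' @param stabilization_factor decay attenuation in the mutant for the
#'   maternal-decay classes A-C (1 = no effect).
#' @param secondary_up constant log2 upshift of zygotic classes D-F in the
#'   mutant, emulating indirect (secondary) effects of the mutation
#'   (0 = none).
#' @param secondary_down_frac fraction of the unclassed (flat) genes given
#'   a `-secondary_up` log2 shift in the mutant (truth class `"down"`),
#'   emulating the mutant's downregulated set so that the two-channel
#'   distributions stay roughly balanced under joint quantile
#'   normalisation.
#' @param target_fraction_decay,target_fraction_other fraction of decay
#'   class (A-C) and of remaining genes flagged as direct targets in the
#'   ground truth (the emulated RIP list).
#' @param n_probes,probe_len_range RNAcompete pool size and probe length
#'   range.
#' @param affinity_kmer hidden affinity 7-mer.
#' @param affinity_beta intensity increment per affinity-7-mer occurrence.
#' @param rnacompete_baseline,rnacompete_noise_sd probe intensity baseline
#'   and noise sd.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L, n_targets = min(300L, n_genes %/% 2L),
                       n_replicates = 3L,
                       enrichment_fold = 2, noise_sd = 0.25,
                       baseline_mean = 8, baseline_sd = 1.5,
                       motif = "UUGUUAU", sites_per_target = 2L,
                       accessibility_high = 0.9, accessibility_low = 0.1,
                       utr5_len = 50L, orf_len = 300L, utr3_len = 200L,
                       class_proportions = stats::setNames(rep(1 / 8, 6), LETTERS[1:6]),
                       timecourse_amplitude = 3, stabilization_factor = 3,
                       secondary_up = 1, secondary_down_frac = 0.15,
                       target_fraction_decay = 0.85, target_fraction_other = 0.03,
                       n_probes = 6000L, probe_len_range = c(30L, 41L),
                       affinity_kmer = "UUGUUAU", affinity_beta = 2,
                       rnacompete_baseline = 8, rnacompete_noise_sd = 0.25) {
  if (n_targets > n_genes) stop_fmt("n_targets must not exceed n_genes")
  if (enrichment_fold <= 0) stop_fmt("enrichment_fold must be > 0")
  if (noise_sd < 0) stop_fmt("noise_sd must be >= 0")
  for (p in c(accessibility_high, accessibility_low)) {
    if (p < 0 || p > 1) stop_fmt("accessibility probabilities must lie in [0,1]")
  }
  if (length(class_proportions) != 6L || any(class_proportions < 0) ||
      sum(class_proportions) > 1 + 1e-12) {
    stop_fmt("class_proportions must be 6 non-negative fractions summing to <= 1")
  }
  iupac_motif(motif)  # validates
  structure(as.list(environment()), class = "sim_config")
}

.gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate a paired RIP/control experiment
#'
#' Control log2 intensities are Gaussian around a per-gene baseline; RIP
#' intensities add `log2(enrichment_fold)` for planted targets (nothing
#' for non-targets) plus independent per-sample log2 Gaussian noise, so
#' with `noise_sd = 0` every target's per-replicate linear ratio is
#' exactly the enrichment fold. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (an `expr_matrix`, log2) and `truth`
#'   (list: `targets`, `is_target` named logical).
#' @export
simulate_rip_experiment <- function(config = sim_config()) {
  set.seed(config$seed)
  genes <- .gene_ids(config$n_genes)
  targets <- sort(sample(genes, config$n_targets))
  is_target <- stats::setNames(genes %in% targets, genes)
  base <- rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  nr <- config$n_replicates
  vals <- matrix(0, nrow = config$n_genes, ncol = 2L * nr)
  ids <- c(sprintf("RIP_%d", seq_len(nr)), sprintf("CTRL_%d", seq_len(nr)))
  dimnames(vals) <- list(genes, ids)
  shift <- ifelse(is_target, log2(config$enrichment_fold), 0)
  for (r in seq_len(nr)) {
    vals[, r] <- base + shift + rnorm(config$n_genes, 0, config$noise_sd)
    vals[, nr + r] <- base + rnorm(config$n_genes, 0, config$noise_sd)
  }
  samples <- data.frame(sample_id = ids,
                        role = rep(c("RIP", "control"), each = nr),
                        replicate = rep(seq_len(nr), 2L),
                        stringsAsFactors = FALSE)
  list(expr = expr_matrix(vals, samples, log2 = TRUE),
       truth = list(targets = targets, is_target = is_target))
}

## one concrete realization of an IUPAC motif
.realize_motif <- function(letters) {
  paste(vapply(letters, function(l) {
    opts <- IUPAC_RNA[[l]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Simulate a transcriptome with implanted accessible motif sites
#'
#' Background sequences are i.i.d. uniform ACGU with the configured
#' 5'UTR/ORF/3'UTR partition. The first `n_targets` genes (positives)
#' each receive `sites_per_target` non-overlapping concrete realisations
#' of the motif in their 3'UTR (one per equal-width block, random offset);
#' negatives receive no implants. Accessibility tracks are
#' `accessibility_low` everywhere except at the implanted site windows,
#' which get `accessibility_high`. Spontaneous motif matches (in either
#' class) are recorded in the truth, not removed.
#'
#' @param config a [sim_config()]; `n_genes` is the total (positives +
#'   negatives), `n_targets` the number of positives.
#' @return list with `transcripts` (`transcript_set`), `tracks` (named
#'   list of `accessibility_track`s) and `truth` (list: `positives`,
#'   `implants` named list of start positions, `spontaneous` named list
#'   of non-implanted match starts).
#' @export
simulate_transcriptome <- function(config = sim_config(n_genes = 600L)) {
  set.seed(config$seed + 1L)
  motif <- iupac_motif(config$motif)
  w <- motif$width
  k <- config$sites_per_target
  if (k >= 1L && config$utr3_len < k * w) {
    stop_fmt("3'UTR too short (%d nt) for %d site(s) of width %d",
             config$utr3_len, k, w)
  }
  genes <- .gene_ids(config$n_genes)
  positives <- genes[seq_len(config$n_targets)]
  L <- config$utr5_len + config$orf_len + config$utr3_len
  utr5 <- if (config$utr5_len > 0L) c(1L, config$utr5_len)
  orf <- if (config$orf_len > 0L) {
    c(config$utr5_len + 1L, config$utr5_len + config$orf_len)
  }
  utr3 <- if (config$utr3_len > 0L) c(config$utr5_len + config$orf_len + 1L, L)
  transcripts <- vector("list", config$n_genes)
  tracks <- vector("list", config$n_genes)
  implants <- list(); spontaneous <- list()
  block <- config$utr3_len %/% max(k, 1L)
  for (i in seq_along(genes)) {
    seqint <- sample.int(4L, L, replace = TRUE)
    p <- rep(config$accessibility_low, L)
    if (genes[i] %in% positives && k >= 1L) {
      starts <- integer(k)
      for (b in seq_len(k)) {
        off <- sample.int(block - w + 1L, 1L)
        starts[b] <- utr3[1] - 1L + (b - 1L) * block + off
        inst <- .realize_motif(motif$letters)
        seqint[starts[b]:(starts[b] + w - 1L)] <- match(strsplit(inst, "")[[1]], VALID_RNA)
      }
      implants[[genes[i]]] <- starts
      p[starts + w - 1L] <- config$accessibility_high
    }
    seq_chr <- paste(VALID_RNA[seqint], collapse = "")
    transcripts[[i]] <- transcript_record(genes[i], genes[i], seq_chr,
                                          utr5 = utr5, orf = orf, utr3 = utr3)
    tracks[[i]] <- accessibility_track(genes[i], w, p)
    hits <- .match_starts(seqint, motif$letters)
    sp <- setdiff(hits, implants[[genes[i]]] %||% integer(0))
    if (length(sp) > 0L) spontaneous[[genes[i]]] <- sp
  }
  names(transcripts) <- genes
  names(tracks) <- genes
  class(transcripts) <- "transcript_set"
  list(transcripts = transcripts, tracks = tracks,
       truth = list(positives = positives, implants = implants,
                    spontaneous = spontaneous, motif = motif_string(motif)))
}

## standardized wild-type archetype shapes over four ordered timepoints:
## A decline then re-expression; B monotone decline; C flat then decline;
## D/E/F zygotic induction with maximum at t2/t3/t4.
.tc_archetypes <- function() {
  rbind(A = c(1.0, 0.4, 0.2, 0.8),
        B = c(1.0, 0.7, 0.4, 0.2),
        C = c(1.0, 1.0, 0.45, 0.15),
        D = c(0.2, 1.0, 0.6, 0.4),
        E = c(0.2, 0.6, 1.0, 0.7),
        F = c(0.1, 0.3, 0.7, 1.0))
}

#' Simulate a two-genotype four-timepoint expression course
#'
#' Wild-type log2 profiles follow one of six archetype shapes (classes
#' A-F: three maternal-decay shapes, three zygotic-induction shapes) or a
#' flat profile for unclassed genes, scaled by `timecourse_amplitude`
#' around a per-gene baseline, with log2 Gaussian noise per measurement.
#' In the mutant, classes A-C have their deviation from the initial
#' timepoint divided by `stabilization_factor` (1 = identical to wild
#' type), emulating loss of RBP-mediated decay. The ground truth also
#' carries an emulated direct-target list (a configured fraction of A-C
#' plus a background rate elsewhere).
#'
#' @param config a [sim_config()].
#' @return list with `expr` (an `expr_matrix` over
#'   2 genotypes x 4 timepoints x `n_replicates`) and `truth` (list:
#'   `class` named character (A-F, "down" or "flat"), `targets`,
#'   `archetypes`).
#' @export
simulate_timecourse <- function(config = sim_config(n_genes = 1200L)) {
  set.seed(config$seed + 2L)
  genes <- .gene_ids(config$n_genes)
  shapes <- .tc_archetypes()
  prop <- config$class_proportions
  n_cls <- round(prop * config$n_genes)
  n_flat <- config$n_genes - sum(n_cls)
  n_down <- round(config$secondary_down_frac * n_flat)
  lab <- c(rep(rownames(shapes), n_cls), rep("down", n_down),
           rep("flat", n_flat - n_down))
  lab <- sample(lab)
  names(lab) <- genes
  base <- rnorm(config$n_genes, config$baseline_mean, 0.5)
  amp <- config$timecourse_amplitude
  nr <- config$n_replicates
  tps <- paste0("t", 1:4)
  ids <- as.vector(outer(outer(tps, seq_len(nr),
                               function(t, r) paste0(t, "_r", r)),
                         c("WT", "MUT"), function(a, g) paste0(g, "_", a)))
  vals <- matrix(0, nrow = config$n_genes, ncol = length(ids),
                 dimnames = list(genes, ids))
  meta <- do.call(rbind, strsplit(ids, "_"))
  samples <- data.frame(sample_id = ids,
                        role = ifelse(meta[, 1] == "WT", "wildtype", "mutant"),
                        replicate = as.integer(sub("r", "", meta[, 3])),
                        timepoint = meta[, 2],
                        stringsAsFactors = FALSE)
  s <- config$stabilization_factor
  for (i in seq_along(genes)) {
    shp <- if (lab[i] %in% c("flat", "down")) rep(0.5, 4) else shapes[lab[i], ]
    wt_mu <- base[i] + amp * shp
    mut_shp <- if (lab[i] %in% c("A", "B", "C")) {
      shp[1] + (shp - shp[1]) / s
    } else shp
    mut_mu <- base[i] + amp * mut_shp
    if (lab[i] %in% c("D", "E", "F")) mut_mu <- mut_mu + config$secondary_up
    if (lab[i] == "down") mut_mu <- mut_mu - config$secondary_up
    for (col in seq_along(ids)) {
      mu <- if (samples$role[col] == "wildtype") wt_mu else mut_mu
      vals[i, col] <- mu[match(samples$timepoint[col], tps)] +
        rnorm(1, 0, config$noise_sd)
    }
  }
  is_decay <- lab %in% c("A", "B", "C")
  pick <- runif(config$n_genes) < ifelse(is_decay, config$target_fraction_decay,
                                         config$target_fraction_other)
  targets <- sort(genes[pick])
  list(expr = expr_matrix(vals, samples, log2 = TRUE),
       truth = list(class = lab, targets = targets, archetypes = shapes))
}

#' Simulate an RNAcompete-style probe pool
#'
#' Probe sequences are uniform ACGU with lengths drawn from
#' `probe_len_range`; intensity = baseline + beta x (occurrences of the
#' affinity 7-mer, overlapping counted) + Gaussian noise, floored at 0.
#'
#' @param config a [sim_config()].
#' @return list with `pool` (data.frame: `probe_id`, `sequence`,
#'   `intensity`) and `truth` (list: `affinity_kmer`, `counts`).
#' @export
simulate_rnacompete <- function(config = sim_config()) {
  set.seed(config$seed + 3L)
  km <- iupac_motif(config$affinity_kmer)
  lens <- sample(seq(config$probe_len_range[1], config$probe_len_range[2]),
                 config$n_probes, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(VALID_RNA[sample.int(4L, L, replace = TRUE)], collapse = "")
  }, character(1))
  counts <- vapply(seqs, function(s) length(.match_starts(.encode_rna(s), km$letters)),
                   integer(1), USE.NAMES = FALSE)
  intensity <- pmax(0, config$rnacompete_baseline + config$affinity_beta * counts +
                      rnorm(config$n_probes, 0, config$rnacompete_noise_sd))
  pool <- data.frame(probe_id = sprintf("p%05d", seq_len(config$n_probes)),
                     sequence = seqs, intensity = intensity,
                     stringsAsFactors = FALSE)
  list(pool = pool,
       truth = list(affinity_kmer = motif_string(km), counts = counts))
}
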