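## End-to-end orchestration of the three study arms: RIP target calling +
## motif discovery, the mutant/wild-type decay time course, and the
## in-vitro probe-pool arm. Each runner returns a structured result list
## with a machine-readable run report and optionally writes TSV outputs.

#' Pipeline configuration
#'
#' Houses the pipeline's fixed constants with their defaults: the target
#' rule (fold >= 1.5, FDR < 5%), the unchanged rule (within 1.1-fold,
#' FDR > 50%), the folding-window parameters (W = 80, L = 40), the motif
#' search (10 seeds, widths up to 9, 3 x 10 cross-validation), the
#' clustering block (k = 6, 100 restarts) and the annotation floor
#' (background sets of more than 25 genes). All values are echoed into
#' every run report.
#'
#' @param seed global seed; per-stage seeds derive from it by fixed
#'   offsets.
#' @param min_fold,max_fdr target-calling rule.
#' @param unchanged_fold,unchanged_fdr unchanged-set rule.
#' @param min_set_size annotation-enrichment background floor.
#' @param k,n_restarts clustering block.
#' @param motif a [motif_params()] (its seed is overridden by `seed`).
#' @param do_cv run cross-validated motif discovery in the RIP arm.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, min_fold = 1.5, max_fdr = 0.05,
                            unchanged_fold = 1.1, unchanged_fdr = 0.5,
                            min_set_size = 26L, k = 6L, n_restarts = 100L,
                            motif = motif_params(), do_cv = TRUE) {
  stopifnot(min_fold > 0, max_fdr > 0, max_fdr < 1,
            unchanged_fold > 1, unchanged_fdr > 0, k >= 2L, n_restarts >= 1L)
  motif$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), min_fold = min_fold, max_fdr = max_fdr,
                 unchanged_fold = unchanged_fold, unchanged_fdr = unchanged_fdr,
                 min_set_size = as.integer(min_set_size), k = as.integer(k),
                 n_restarts = as.integer(n_restarts), motif = motif,
                 do_cv = isTRUE(do_cv)),
            class = "pipeline_config")
}

.report_add <- function(report, stage, ...) {
  report[[stage]] <- list(...)
  report
}

## one RIP experiment: normalize, expressed set, paired SAM, targets,
## negatives
.rip_calls <- function(em, config) {
  norm <- quantile_normalize(em)
  expressed <- define_expressed(norm)
  sub <- norm$values[expressed, , drop = FALSE]
  design <- sam_design(group = factor(norm$samples$role, levels = c("control", "RIP")),
                       pair = norm$samples$replicate)
  fold <- fold_enrichment(sub, design, log2 = TRUE)
  sam <- permutation_fdr(sub, design,
                         sam_params("two_class_paired", seed = config$seed),
                         fold = fold)
  calls <- call_targets(sam, config$min_fold, config$max_fdr)
  list(normalized = norm, expressed = expressed, sam = sam,
       targets = calls$genes, report = calls$report,
       negatives = define_negative_set(sam))
}

#' Run the RIP-Chip arm
#'
#' For each experiment (e.g. one per RNA-binding protein): quantile
#' normalisation, expressed-set definition, paired SAM with permutation
#' FDR, target calling (fold >= 1.5 and FDR < 5%), the negatively
#' enriched control set, accessibility-weighted motif discovery with
#' optional 3 x 10 cross-validation, and per-region motif enrichment.
#' With two experiments, additionally: target-overlap Fisher test on the
#' shared expressed background, quadrant-excluded Spearman correlation of
#' the two fold vectors, and co-target motif co-occurrence AUROCs using
#' `max(score_A, score_B)` as the "either" and `min(score_A, score_B)`
#' as the "both" combiner.
#'
#' @param experiments named list of `expr_matrix` objects (one or two
#'   paired RIP/control experiments).
#' @param transcripts a `transcript_set` covering the assayed genes.
#' @param tracks named list of `accessibility_track`s (or `NULL` for
#'   unweighted scoring).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for TSV outputs and the JSON run
#'   report.
#' @return list of class `rip_arm_result` with one entry per experiment
#'   (`expressed`, `targets`, `negatives`, `sam`, `discovery`, `cv`,
#'   `region_enrichment`) plus `overlap`, `spearman`, `cotarget_auroc`
#'   when two experiments are given, and `report`.
#' @export
run_rip_arm <- function(experiments, transcripts, tracks = NULL,
                        config = pipeline_config(), out_dir = NULL) {
  if (inherits(experiments, "expr_matrix")) experiments <- list(experiment = experiments)
  report <- list(config = unclass(config)[setdiff(names(config), "motif")])
  corpus <- motif_corpus(transcripts, tracks)
  res <- list()
  for (nm in names(experiments)) {
    calls <- .rip_calls(experiments[[nm]], config)
    disc <- discover_motif(corpus, calls$targets, calls$negatives, config$motif)
    cv <- if (config$do_cv) {
      cross_validate(corpus, calls$targets, calls$negatives, config$motif)
    }
    re <- region_enrichment(calls$targets, calls$negatives, disc$motif, corpus,
                            m_tests = 4L * length(experiments))
    res[[nm]] <- list(expressed = calls$expressed, targets = calls$targets,
                      negatives = calls$negatives, sam = calls$sam,
                      discovery = disc, cv = cv, region_enrichment = re)
    report <- .report_add(report, paste0("experiment_", nm),
                          n_expressed = length(calls$expressed),
                          n_targets = length(calls$targets),
                          n_negatives = length(calls$negatives),
                          motif = motif_string(disc$motif),
                          training_auroc = disc$training_auroc,
                          cv_mean_auroc = if (!is.null(cv)) cv$mean_auroc else NA)
  }
  if (length(experiments) == 2L) {
    nms <- names(experiments)
    shared <- intersect(res[[1]]$expressed, res[[2]]$expressed)
    res$overlap <- compare_lists(intersect(res[[1]]$targets, shared),
                                 intersect(res[[2]]$targets, shared), shared)
    f1 <- stats::setNames(res[[1]]$sam$fold, res[[1]]$sam$gene_id)[shared]
    f2 <- stats::setNames(res[[2]]$sam$fold, res[[2]]$sam$gene_id)[shared]
    res$spearman <- spearman_quadrant_excluded(f1, f2)
    co <- intersect(res[[1]]$targets, res[[2]]$targets)
    non <- intersect(res[[1]]$negatives, res[[2]]$negatives)
    if (length(co) > 0L && length(non) > 0L) {
      sA <- score_transcripts(corpus, res[[1]]$discovery$motif)
      sB <- score_transcripts(corpus, res[[2]]$discovery$motif)
      comb <- list(first = sA, second = sB,
                   either = pmax(sA, sB), both = pmin(sA, sB))
      names(comb)[1:2] <- nms
      res$cotarget_auroc <- vapply(comb, function(s) {
        .auroc_value(s[co], s[non])
      }, numeric(1))
    }
    report <- .report_add(report, "overlap",
                          n_overlap = res$overlap$n_overlap,
                          p_value = res$overlap$p_value,
                          spearman_rho = res$spearman$rho,
                          combiners = "either=max, both=min")
  }
  res$report <- report
  class(res) <- "rip_arm_result"
  if (!is.null(out_dir)) .write_rip_outputs(res, names(experiments), out_dir)
  res
}

.write_rip_outputs <- function(res, nms, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in nms) {
    r <- res[[nm]]
    write.table(r$sam, file.path(out_dir, paste0(nm, "_targets.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(r$expressed, file.path(out_dir, paste0(nm, "_expressed.txt")))
    writeLines(motif_string(r$discovery$motif),
               file.path(out_dir, paste0(nm, "_motif.txt")))
    write.table(r$region_enrichment,
                file.path(out_dir, paste0(nm, "_region_enrichment.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(r$cv)) {
      write.table(r$cv$folds, file.path(out_dir, paste0(nm, "_cv.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(res$report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(NULL)
}

#' Run the time-course arm
#'
#' Quantile-normalises the two-genotype four-timepoint matrix, defines
#' the expressed set as the union of per-condition one-class calls, runs
#' per-timepoint unpaired SAM (mutant vs wild type) for up/down calls at
#' FDR < 5%, derives the unchanged set (within 1.1-fold and FDR > 50% at
#' every timepoint), clusters the union of upregulated genes on their
#' wild-type profiles by consensus k-means (k = 6, 100 restarts), tags
#' cluster archetypes, and — when a target list is supplied — tests each
#' class for Fisher overlap with the targets (BH-corrected within the
#' run) and, when a motif and corpus are supplied, for motif enrichment
#' versus the unchanged set (Bonferroni-corrected WMW).
#'
#' @param em an `expr_matrix` with roles `wildtype`/`mutant` and ordered
#'   timepoint labels.
#' @param config a [pipeline_config()].
#' @param target_list optional character vector of direct-target gene ids
#'   (e.g. RIP-Chip targets).
#' @param motif,corpus optional `iupac_motif` and [motif_corpus()] for
#'   class-wise motif enrichment against the unchanged set.
#' @param out_dir optional output directory.
#' @return list of class `timecourse_arm_result`: `expressed`,
#'   `up`/`down` (per-timepoint lists), `up_union`, `unchanged`,
#'   `clusters` (a `cluster_result`), `class_overlap`,
#'   `class_motif_enrichment`, `report`.
#' @export
run_timecourse_arm <- function(em, config = pipeline_config(),
                               target_list = NULL, motif = NULL, corpus = NULL,
                               out_dir = NULL) {
  tps <- unique(em$samples$timepoint)
  if (!identical(tps, sort(tps))) stop_fmt("timepoints must be ordered")
  norm <- quantile_normalize(em)
  expressed <- define_expressed(norm)
  sub <- norm$values[expressed, , drop = FALSE]
  up <- list(); down <- list(); unchanged_tp <- list(); sams <- list()
  for (tp in sort(tps)) {
    cols <- em$samples$timepoint == tp
    design <- sam_design(group = factor(norm$samples$role[cols],
                                        levels = c("wildtype", "mutant")))
    xi <- sub[, cols, drop = FALSE]
    fold <- fold_enrichment(xi, design, log2 = TRUE)
    sam <- permutation_fdr(xi, design,
                           sam_params("two_class_unpaired", seed = config$seed),
                           fold = fold)
    sams[[tp]] <- sam
    up[[tp]] <- sam$gene_id[sam$d > 0 & sam$fdr < config$max_fdr]
    down[[tp]] <- sam$gene_id[sam$d < 0 & sam$fdr < config$max_fdr]
    unchanged_tp[[tp]] <- define_unchanged(sam, config$unchanged_fold,
                                           config$unchanged_fdr)
  }
  up_union <- sort(unique(unlist(up)))
  unchanged <- sort(Reduce(intersect, unchanged_tp))
  clusters <- NULL; class_overlap <- NULL; class_motif <- NULL
  if (length(up_union) >= config$k) {
    prof <- profile_set(norm, role = "wildtype", genes = up_union)
    clusters <- consensus_clusters(prof, k = config$k,
                                   n_restarts = config$n_restarts,
                                   seed = config$seed)
    if (!is.null(target_list)) {
      rows <- lapply(seq_len(config$k), function(cl) {
        members <- names(clusters$labels)[clusters$labels == cl]
        ov <- compare_lists(members, intersect(target_list, expressed), expressed)
        data.frame(cluster = cl, archetype = clusters$archetype[cl],
                   n_members = length(members), n_target_overlap = ov$n_overlap,
                   odds_ratio = ov$odds_ratio, p_value = ov$p_value,
                   stringsAsFactors = FALSE)
      })
      class_overlap <- do.call(rbind, rows)
      class_overlap$q_value <- bh_fdr(class_overlap$p_value)
    }
    if (!is.null(motif) && !is.null(corpus)) {
      sc <- score_transcripts(corpus, motif)
      rows <- lapply(seq_len(config$k), function(cl) {
        members <- intersect(names(clusters$labels)[clusters$labels == cl],
                             corpus$genes)
        ctrl <- intersect(unchanged, corpus$genes)
        if (length(members) == 0L || length(ctrl) == 0L) return(NULL)
        ar <- auroc(sc[members], sc[ctrl])
        data.frame(cluster = cl, archetype = clusters$archetype[cl],
                   auroc = ar$auroc, p_value = ar$p_value,
                   p_bonferroni = min(1, ar$p_value * config$k),
                   stringsAsFactors = FALSE)
      })
      class_motif <- do.call(rbind, rows)
    }
  }
  report <- list(config = unclass(config)[setdiff(names(config), "motif")],
                 n_expressed = length(expressed),
                 n_up = vapply(up, length, integer(1)),
                 n_down = vapply(down, length, integer(1)),
                 n_up_union = length(up_union),
                 n_unchanged = length(unchanged),
                 modal_frequency = if (!is.null(clusters)) clusters$modal_frequency else NA)
  res <- list(expressed = expressed, sams = sams, up = up, down = down,
              up_union = up_union, unchanged = unchanged, clusters = clusters,
              class_overlap = class_overlap,
              class_motif_enrichment = class_motif, report = report)
  class(res) <- "timecourse_arm_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(clusters)) {
      write.table(data.frame(gene_id = names(clusters$labels),
                             cluster = clusters$labels,
                             archetype = clusters$archetype[clusters$labels]),
                  file.path(out_dir, "classes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(cluster = rownames(clusters$centroids),
                             clusters$centroids),
                  file.path(out_dir, "centroids.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  res
}

#' Alignment-based compatibility of two IUPAC motifs
#'
#' Slides one motif along the other over all ungapped offsets with at
#' least `min_overlap` aligned positions and reports the best offset —
#' the one maximising the number of aligned positions whose allowed base
#' sets intersect. The motifs are called compatible when some offset
#' makes every aligned position intersect.
#'
#' @param a,b `iupac_motif`s or IUPAC strings.
#' @param min_overlap minimum aligned positions (default 4).
#' @return list: `compatible`, `offset`, `n_overlap`, `n_agree`.
#' @export
motif_agreement <- function(a, b, min_overlap = 4L) {
  a <- iupac_motif(a); b <- iupac_motif(b)
  best <- list(compatible = FALSE, offset = NA_integer_, n_overlap = 0L,
               n_agree = -1L)
  for (off in seq(-(b$width - min_overlap), a$width - min_overlap)) {
    js <- seq_len(b$width)
    ok <- js + off >= 1L & js + off <= a$width
    if (sum(ok) < min_overlap) next
    inter <- mapply(function(x, y) length(intersect(IUPAC_RNA[[x]], IUPAC_RNA[[y]])) > 0L,
                    b$letters[js[ok]], a$letters[js[ok] + off])
    n_agree <- sum(inter)
    if (n_agree > best$n_agree ||
        (n_agree == best$n_agree && all(inter) && !best$compatible)) {
      best <- list(compatible = all(inter), offset = off,
                   n_overlap = sum(ok), n_agree = n_agree)
    }
  }
  best
}

#' Run the in-vitro probe-pool arm
#'
#' Computes 7-mer Z-scores from probe intensities, assembles the aligned
#' consensus motif from the top 7-mers, and — when an in-vivo motif is
#' supplied — reports whether the two motifs are compatible over their
#' aligned core.
#'
#' @param pool probe pool data.frame (`probe_id`, `sequence`,
#'   `intensity`).
#' @param trim_fraction trimmed-mean tail fraction (default 0.25).
#' @param top_n 7-mers stacked into the consensus (default 10).
#' @param invivo_motif optional `iupac_motif`/string for the agreement
#'   report.
#' @param out_dir optional output directory.
#' @return list of class `rnacompete_arm_result`: `kmer_table`,
#'   `assembled`, `agreement`, `report`.
#' @export
run_rnacompete_arm <- function(pool, trim_fraction = 0.25, top_n = 10L,
                               invivo_motif = NULL, out_dir = NULL) {
  if (is.null(pool) || nrow(pool) == 0L) stop_fmt("empty probe pool")
  kt <- kmer_zscores(pool, trim_fraction)
  asm <- assemble_motif(kt, top_n = top_n)
  agreement <- if (!is.null(invivo_motif)) motif_agreement(asm$motif, invivo_motif)
  report <- list(n_probes = nrow(pool), trim_fraction = trim_fraction,
                 top_n = top_n, motif = motif_string(asm$motif),
                 top_kmer = kt$kmer[1], top_z = kt$z[1],
                 compatible_with_invivo = if (!is.null(agreement)) agreement$compatible else NA)
  res <- list(kmer_table = kt, assembled = asm, agreement = agreement,
              report = report)
  class(res) <- "rnacompete_arm_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(kt, file.path(out_dir, "kmer_z.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(motif_string(asm$motif), file.path(out_dir, "motif.txt"))
    write.table(data.frame(base = rownames(asm$pwm), asm$pwm),
                file.path(out_dir, "pwm.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  res
}
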