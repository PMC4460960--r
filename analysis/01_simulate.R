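#!/usr/bin/env Rscript
# Generate the synthetic study inputs with ground truth and write them in
# the pipeline's standard on-disk formats under results/data/. Every
# downstream driver reads these files back through the package's readers,
# so the full I/O surface is exercised.

suppressPackageStartupMessages(library(ripmzt))

seed <- 1L
out <- "results/data"
dir.create(file.path(out, "lunp"), showWarnings = FALSE, recursive = TRUE)

## Two paired RIP/control experiments (three replicates each) with
## partially overlapping planted target sets, emulating two RNA-binding
## proteins assayed against a shared embryo transcriptome.
cfgA <- sim_config(seed = seed, n_genes = 600, n_targets = 150, enrichment_fold = 3)
simA <- simulate_rip_experiment(cfgA)
genes <- rownames(simA$expr$values)
set.seed(seed + 100)
targetsB <- sort(c(sample(simA$truth$targets, 75),
                   sample(setdiff(genes, simA$truth$targets), 75)))
base <- simA$expr$values[, 4:6]
ripB <- base + ifelse(genes %in% targetsB, log2(3), 0) +
  matrix(rnorm(length(base), 0, cfgA$noise_sd), nrow = length(genes))
ctlB <- base + matrix(rnorm(length(base), 0, cfgA$noise_sd), nrow = length(genes))
valsB <- cbind(ripB, ctlB)
colnames(valsB) <- colnames(simA$expr$values)
emB <- expr_matrix(valsB, simA$expr$samples, log2 = TRUE)

write_expression_tsv(simA$expr, file.path(out, "ripA_expression.tsv"),
                     file.path(out, "ripA_samples.tsv"))
write_expression_tsv(emB, file.path(out, "ripB_expression.tsv"),
                     file.path(out, "ripB_samples.tsv"))

## Transcriptome with UUGUUAU implanted at accessible 3'UTR sites of the
## experiment-A targets (the in-vivo binding substrate).
trs_bg <- simulate_transcriptome(sim_config(seed = seed, n_genes = 600,
                                            n_targets = 0, sites_per_target = 0L))
trs_sig <- simulate_transcriptome(sim_config(seed = seed, n_genes = 600,
                                             n_targets = 600))
transcripts <- trs_bg$transcripts
tracks <- trs_bg$tracks
for (g in simA$truth$targets) {
  transcripts[[g]] <- trs_sig$transcripts[[g]]
  tracks[[g]] <- trs_sig$tracks[[g]]
}
class(transcripts) <- "transcript_set"
write_transcripts(transcripts, file.path(out, "transcripts.fa"),
                  file.path(out, "regions.tsv"))
for (g in names(tracks)) {
  write_lunp(tracks[[g]], file.path(out, "lunp", paste0(g, "_lunp")))
}

## Mutant / wild-type four-timepoint course at realistic proportions
## (~12% of genes upregulated, balanced by a downregulated fraction).
cfgT <- sim_config(seed = seed, n_genes = 2000, noise_sd = 0.15,
                   class_proportions = setNames(rep(0.02, 6), LETTERS[1:6]))
simT <- simulate_timecourse(cfgT)
write_expression_tsv(simT$expr, file.path(out, "timecourse_expression.tsv"),
                     file.path(out, "timecourse_samples.tsv"))

## RNAcompete-style probe pool with a hidden UUGUUAU affinity.
simR <- simulate_rnacompete(sim_config(seed = seed))
write.table(simR$pool, file.path(out, "probe_pool.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## Ground truth for the recovery summaries of the downstream drivers.
truth <- data.frame(
  gene_id = genes,
  rip_target_A = genes %in% simA$truth$targets,
  rip_target_B = genes %in% targetsB)
write.table(truth, file.path(out, "truth_rip.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = names(simT$truth$class),
                       class = simT$truth$class,
                       direct_target = names(simT$truth$class) %in% simT$truth$targets),
            file.path(out, "truth_timecourse.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(simR$truth$affinity_kmer, file.path(out, "truth_affinity_kmer.txt"))

cat(sprintf("wrote %d genes x 2 RIP experiments, %d transcripts (+lunp tracks),\n",
            length(genes), length(transcripts)))
cat(sprintf("a %d-gene time course and a %d-probe pool under %s/\n",
            nrow(simT$expr$values), nrow(simR$pool), out))
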