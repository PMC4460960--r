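#!/usr/bin/env Rscript
# Probe-pool arm: 7-mer Z-scores, consensus-motif assembly from the top
# 7-mers, pool coverage, and the agreement report against the in-vivo
# consensus NNUGUUDNN.

suppressPackageStartupMessages(library(ripmzt))

dat <- "results/data"
out <- "results/rnacompete"

pool <- read.delim(file.path(dat, "probe_pool.tsv"))
plant <- readLines(file.path(dat, "truth_affinity_kmer.txt"))

res <- run_rnacompete_arm(pool, invivo_motif = "NNUGUUDNN", out_dir = out)

cov <- pool_coverage_report(pool, k = 7)
cat(sprintf("pool: %d probes | 7-mer coverage min/median/max = %d/%s/%d\n",
            nrow(pool), cov$min, format(cov$median), cov$max))
cat("top 7-mers by Z:\n")
print(head(res$kmer_table[, c("kmer", "n_probes", "summary", "z")], 5))
cat(sprintf("assembled motif: %s | hidden affinity 7-mer: %s | compatible: %s\n",
            motif_string(res$assembled$motif), plant,
            motif_agreement(res$assembled$motif, plant)$compatible))
cat(sprintf("agreement with in-vivo consensus NNUGUUDNN: %s\n",
            res$agreement$compatible))
cat("outputs under", out, "\n")
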