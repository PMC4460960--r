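---
title: "Methods: RIP-Chip target calling, accessibility-aware motif discovery, and decay-class analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RIP-Chip target calling, accessibility-aware motif discovery, and decay-class analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripmzt)
```

# The problem

During the maternal-to-zygotic transition (MZT), early embryos eliminate a
large fraction of their maternally deposited mRNAs while activating zygotic
transcription. Sequence-specific RNA-binding proteins (RBPs) drive much of
this clearance: they recognise short, often structurally accessible elements
in target 3'UTRs and recruit translational-repression and decay machinery.
`ripmzt` implements the computational arc of a study of this kind for two
Drosophila RBPs (a TRIM-NHL protein and a PUF-family protein): identify the
RBP-associated transcripts from co-immunoprecipitation microarrays
(RIP-Chip), learn the binding motif that distinguishes targets from
co-expressed non-targets, corroborate it with an in-vitro probe-pool binding
assay, and show that targets are stabilised — in defined kinetic classes —
when the RBP is removed.

Every stage is paired with a seeded synthetic-data generator that emulates
the statistical structure the stage assumes, with ground truth, so the whole
pipeline is testable end to end without any external download.

# Differential enrichment: the SAM statistic and its permutation FDR

Target calling and the time-course up/down calls use a moderated difference
statistic on log2 intensities,

$$ d_i = \frac{r_i}{s_i + s_0}, $$

where $r_i$ is the variant-specific effect (difference of group means;
mean of paired differences; or mean minus a reference $\mu_0$ for the
one-class "expressed" test), $s_i$ the matching standard error, and $s_0$ a
fudge factor that prevents low-variance genes from dominating. By default
$s_0$ is chosen by a grid search over percentiles of $\{s_i\}$, minimising
the coefficient of variation of the spread of $d$ across bins of $s$ — the
classical calibration for this family of statistics; fixed-percentile and
zero strategies are available for tests and worked examples.

Significance is assessed by permutation, holding $s_0$ fixed at its
observed-data value:

* unpaired two-class: all (or a seeded sample of) group-label
  reassignments;
* paired two-class: sign flips of the per-pair difference vectors ($2^n$,
  enumerable and therefore exhaustive at $n = 3$ replicates, giving 8
  permutations);
* one-class: sign flips of the per-sample deviations from $\mu_0$ — the
  standard exact one-sample scheme, chosen over sample-resampling because it
  is exhaustive at small $n$ and mirrors the paired variant's logic.

For a cutoff $c$ the estimated false discovery rate is the median across
permutations of the count of permuted $|d|$ values at or above $c$, divided
by the observed count, capped at 1. Each gene receives the FDR at its own
$|d|$, monotonised by a running minimum over decreasing $|d|$ (the q-value
convention) so that thresholding is well defined. No null-proportion
($\pi_0$) correction is applied; with it the estimates would only become
smaller, so control is conservative.

Three decision rules sit on top:

* **targets**: linear fold enrichment $\ge 1.5$ (arithmetic mean of
  per-replicate linear ratios; the geometric mean is available and the
  choice is recorded) *and* FDR < 5%;
* **expressed**: one-class $d > 0$ at FDR < 5% against the condition's
  grand mean, united across conditions (roles x timepoints);
* **unchanged**: linear fold strictly inside $(1/1.1, 1.1)$ *and*
  FDR > 50%, evaluated per timepoint; the pipeline's pooled control set is
  the intersection across timepoints.

The negatively enriched control set for motif discovery is the expressed
genes with paired $d < 0$ (enriched in the control immunoprecipitate); no
fold or FDR threshold is applied there, matching the qualitative
"negatively enriched" definition.

# Accessibility-weighted motif discovery

## Scoring

A motif is a degenerate IUPAC string (width $\ge 4$). A transcript's score
under a motif is the sum, over all IUPAC-compatible (overlapping) match
windows, of the *accessibility* of the window: the probability, under a
local RNA-folding model, that the $U$-nucleotide window ending at the match
end is entirely unpaired. Transcripts without a match score zero.
Accessibility tracks follow the RNAplfold `_lunp` convention with the
standard local-folding parameters $W = 80$ (folding window) and $L = 40$
(maximum pairing span), $U$ set to the motif width; the whole transcript is
folded so sites flanking the start/stop codons are handled correctly.
Undefined entries (the first $U - 1$ positions, or `NA` rows) contribute 0
and are tallied. Tracks carry a single $U$; when greedy refinement widens a
motif by one flank the track entry at the window end is reused for the
widened width — a documented approximation (a real `_lunp` file carries one
column per width, and the reader extracts whichever column is requested).
When no folding output is available, a constant-probability fallback
(reducing scores to weighted match counts) and a GC-content heuristic
(accessibility $0.9 - 0.8 \cdot \mathrm{gc}$ over an 80-nt neighbourhood)
are provided.

## Evaluation

Discrimination between positives (targets) and negatives (co-expressed
non-targets) is measured by the AUROC of the transcript scores: the
probability that a random positive outscores a random negative, ties
counted one half. Significance comes from the two-sided
Wilcoxon–Mann–Whitney test — exact enumeration of labelings when the
combined sample is at most 12 (correct under ties), the tie-corrected
normal approximation otherwise.

## Search

The discovery algorithm optimises exactly this objective:

1. rank all $4^7$ exact 7-mers by the AUROC of their accessibility-weighted
   scores on the training genes (ties: more matched positives, then
   lexicographic);
2. take the top 10 as seeds;
3. greedily refine each seed: sweep positions — including up to one flank
   position on each side, to a maximum width of 9 — and at each position
   keep the best IUPAC substitution that *strictly* increases the training
   AUROC, repeating until a full sweep changes nothing;
4. return the refined motif with the highest training AUROC (ties: fewer
   degenerate letters, then lexicographic).

The procedure is deterministic, is a greedy ascent (the result never scores
below its seed), and emits degenerate consensus strings of the
`NNUGUUDNN` / `UGUANAKW` kind. Raw unpaired probabilities are used without
transformation. Predictive power is reported as 3 x 10 cross-validation:
positives and negatives are independently shuffled and dealt into 10
near-equal bins (stratified, so each fold preserves the class ratio), a
motif is trained on 9 bins and evaluated on the held-out bin, and the 30
held-out AUROCs are collected. Per-region enrichment re-scores transcripts
restricted to 5'UTR/ORF/3'UTR/whole and Bonferroni-corrects the four tests.

For efficiency the implementation concatenates all transcripts into one
integer-encoded corpus with per-position transcript, region and
accessibility annotations; candidate motifs are evaluated with incremental
position-indicator vectors, and every scored motif is memoised, so
cross-validation folds over the same corpus reuse earlier scans.

# Probe-pool (in-vitro) arm

Probe intensities from a binding assay against a complex RNA pool are
summarised per 7-mer as the trimmed mean (25% per tail) of the intensities
of probes containing at least one occurrence; Z-scores standardise these
summaries (sample standard deviation, so the scored Z-scores have unit
standard deviation exactly). 7-mers absent from the pool are flagged
unscored. The consensus motif stacks the top 10 7-mers by Z into a
Z-weighted position-frequency matrix after ungapped alignment (offsets up
to 3). The alignment is anchored on the *medoid* of the top 7-mers — the
one with the greatest Z-weighted positional agreement with the rest —
rather than blindly on the top-Z 7-mer, so one spuriously high-Z 7-mer
cannot anchor the consensus; at each column every base with weighted
frequency $\ge 0.25$ enters the IUPAC letter (a uniform column therefore
renders as N) and flanking all-N columns are trimmed.

The synthetic pool draws probes of 30–41 nt uniformly and sets intensity =
baseline + $\beta \cdot$ (occurrences of a hidden affinity 7-mer) + noise.
The default pool size is 6,000 probes: the real assay's pool guarantees
hundreds of copies of every 7-mer, and 6,000 is the smallest desk scale
whose expected coverage (~11 probes per 7-mer) preserves that guarantee
qualitatively — with far fewer probes a 7-mer seen in a single lucky probe
is statistically indistinguishable from the planted one, and no summary
statistic can rank reliably.

# Decay-class clustering

Genes upregulated in the mutant are partitioned by their wild-type
four-timepoint profiles using k-means under Pearson-correlation distance
($1 - r$). Profiles are z-scored per gene first (Pearson distance is
location/scale-free), centroids are re-standardised member means, seeding
is k-means++-style from the seeded generator, and an emptied cluster is
re-seeded at the point farthest from its assigned centroid. Constant
profiles, for which $r$ is undefined, are routed to an "unclusterable"
bucket. Consensus over 100 seeded restarts declares two runs "the same"
iff their partitions are identical as set partitions (canonical
first-occurrence relabelling); the modal partition and its frequency are
reported, with a warning below 50%. The number of clusters is a parameter
(default 6); a leave-one-timepoint-out figure-of-merit curve (root mean
within-cluster variance of the held-out timepoint, adjusted by
$\sqrt{n/(n-k)}$, averaged over held-out choices) is provided as a
diagnostic only — no elbow is picked automatically.

Recovered centroids are tagged by shape rules on the standardised profile
(tolerance 0.25 on the z scale): maternal-decay family when the profile
starts high and declines — "A-like" if it re-rises at the last timepoint,
"C-like" if it is flat across the first two timepoints before declining,
"B-like" for a monotone decline — and zygotic family when the second
timepoint exceeds the first, subtyped D/E/F by whether the maximum falls at
t2/t3/t4. Ambiguous centroids are tagged "mixed" rather than forced. Tags
are descriptive labels for interpretation, not identities.

# Set statistics

List comparisons use the two-sided Fisher exact test (hypergeometric
convention: all tables with the same margins whose probability does not
exceed the observed one). Families of tests are corrected per invocation
with Benjamini–Hochberg or Bonferroni. The annotation-enrichment engine
takes GMT gene sets with an explicit background universe and, mirroring the
localization-pattern analyses, excludes terms with 25 or fewer background
members by default. Score-distribution comparisons (translation indices,
late/early RPKM ratios) use the tie-corrected two-sided rank-sum test and
report both medians. The correlation between two experiments' fold
enrichments excludes genes depleted (fold < 1) in *both* — the bottom-left
quadrant of the log-log plot, where control-enriched transcripts would
dominate — and computes Spearman's rho with midranks on the remainder (the
coefficient is defined from two remaining points; a p-value requires at
least three).

# What the generators emulate — and what they do not

* **RIP arm**: per-gene log2 baselines (Gaussian, sd 1.5 around 8), a
  multiplicative enrichment for planted targets in the RIP channel, and
  log2-additive Gaussian noise (sd 0.25) per measurement with three paired
  replicates. Real two-channel arrays add probe effects, dye bias and
  spatial artifacts; none are simulated, so passing recovery tests
  demonstrates the statistics, not robustness to array physics.
* **Transcriptome**: uniform-ACGU sequences with a 50/300/200-nt
  5'UTR/ORF/3'UTR partition; two non-overlapping motif instances implanted
  per positive 3'UTR (one per equal block, random offset); accessibility
  0.9 at implanted windows versus 0.1 elsewhere. Spontaneous matches in
  either class are recorded, never scrubbed — the real negative set also
  contains chance matches. Real transcripts have composition bias and
  correlated folding; the synthetic tracks are two-level caricatures.
* **Time course**: six archetype shapes over four timepoints (three
  maternal-decay, three zygotic-induction), amplitude 3 log2 units, with
  the mutant's deviation from the first timepoint divided by a
  stabilisation factor (default 3) for the decay classes, a constant +1
  log2 secondary upshift for the zygotic classes (emulating indirect
  effects, so the upregulated union contains all six classes as in the
  study design), and a downregulated fraction of the unclassed genes
  (default 15%) so that joint quantile normalisation stays roughly
  unbiased — with strongly one-sided changes, rank-based normalisation
  visibly biases null genes' folds, which is a real artifact of the method,
  not of the simulation.
* **Probe pool**: see above; probe-level physics and the coverage-designed
  pool construction are not simulated.

Noise defaults are chosen for testability (clear recovery at desk scale),
not as estimates of any platform's variance.

# Problem sizes and numerical choices

The shipped analyses and tests run at desk scale: 600-transcript corpora
(300 positives / 300 negatives) for motif discovery, 1,000–2,000 genes for
the differential and time-course analyses, 1,200 genes for the six-class
clustering fixture, and 6,000-probe pools. Exact WMW enumeration switches
to the tie-corrected normal approximation above a combined n of 12; Fisher
p-values follow R's `fisher.test` tolerance (ratio `1 + 1e-7`) for float
safety; greedy refinement requires a strict AUROC improvement of more than
`1e-12` to accept a substitution; quantile normalisation resolves ties by
assigning the mean of the tied quantile values. Seeds: every stochastic
stage takes an explicit seed, generators derive their streams from the
config seed by fixed offsets, and cross-validation repeats use
`seed + repeat - 1`.

# Known limitations

* The discovery search is greedy from 7-mer seeds; motifs whose best
  7-mer anchor is weak (highly degenerate motifs with no strong core)
  may be missed. Widths outside 6–9 are not searched.
* Gapped or bipartite motifs and PWM-threshold matching are out of scope;
  matches are exact IUPAC compatibility.
* Gene identifiers are opaque strings; no identifier-version conversion is
  performed, so lists to be compared must already share a namespace.
* The archetype tags encode the four-timepoint design; other designs
  cluster fine but are not tagged.
* Probe-level array preprocessing (background correction, summarisation)
  is upstream of this package: inputs are gene-level matrices.
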