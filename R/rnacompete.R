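## 7-mer intensity summaries, Z-scores and aligned consensus-motif
## assembly from probe-pool intensities (the in-vitro binding arm).

#' Validate a probe pool
#'
#' @param pool data.frame with columns `probe_id`, `sequence` (RNA or DNA;
#'   T converted to U), `intensity` (finite, >= 0).
#' @param len_range allowed probe length range (default 30-41 nt; relax
#'   for toy pools).
#' @return The validated pool (sequences uppercased, T -> U), invisibly
#'   usable downstream.
#' @export
validate_probe_pool <- function(pool, len_range = c(30L, 41L)) {
  need <- c("probe_id", "sequence", "intensity")
  miss <- setdiff(need, names(pool))
  if (length(miss) > 0L) stop_fmt("pool missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(pool) == 0L) stop_fmt("empty probe pool")
  pool$sequence <- gsub("T", "U", toupper(pool$sequence), fixed = TRUE)
  if (!all(is.finite(pool$intensity))) stop_fmt("non-finite probe intensity")
  lens <- nchar(pool$sequence)
  bad <- which(lens < len_range[1] | lens > len_range[2])
  if (length(bad) > 0L) {
    stop_fmt("probe length outside [%d,%d] for %s (and %d more)",
             len_range[1], len_range[2], pool$probe_id[bad[1]], length(bad) - 1L)
  }
  pool
}

## codes (1..4^k) of all k-mer windows of one sequence
.kmer_codes <- function(s, k) {
  v <- .encode_rna(s)
  n <- length(v)
  if (n < k) return(integer(0))
  code <- integer(n - k + 1L)
  for (j in seq_len(k)) code <- code * 4L + (v[j:(n - k + j)] - 1L)
  code + 1L
}

#' 7-mer Z-scores from a probe pool
#'
#' For each 7-mer, the summary intensity is the trimmed mean (dropping
#' `trim_fraction` of the probes from each tail) of the intensities of all
#' probes containing at least one occurrence; the Z-score standardises the
#' summaries (sample sd) over all scored 7-mers. 7-mers occurring in no
#' probe are flagged unscored (`NA`). When all summaries are identical,
#' every Z is 0.
#'
#' @param pool probe pool data.frame (`probe_id`, `sequence`,
#'   `intensity`).
#' @param trim_fraction tail fraction trimmed from the probe-intensity
#'   distribution of each 7-mer, in `[0, 0.5)` (default 0.25).
#' @return data.frame of class `kmer_table`, 16,384 rows: `kmer`, `count`
#'   (total occurrences across probes), `n_probes` (probes containing the
#'   7-mer), `summary`, `z`, ordered by decreasing `z` (unscored last).
#' @export
kmer_zscores <- function(pool, trim_fraction = 0.25) {
  if (nrow(pool) == 0L) stop_fmt("empty probe pool")
  if (trim_fraction < 0 || trim_fraction >= 0.5) stop_fmt("trim_fraction must lie in [0, 0.5)")
  k <- 7L
  pool$sequence <- gsub("T", "U", toupper(pool$sequence), fixed = TRUE)
  per_probe <- lapply(seq_len(nrow(pool)), function(i) .kmer_codes(pool$sequence[i], k))
  occ <- tabulate(unlist(per_probe), nbins = 4L^k)
  dt <- data.table::data.table(
    code = unlist(lapply(per_probe, unique)),
    intensity = rep(pool$intensity, vapply(per_probe, function(x) length(unique(x)), integer(1))))
  agg <- dt[, list(n_probes = .N, summary = mean(intensity, trim = trim_fraction)),
            by = "code"]
  summary_all <- rep(NA_real_, 4L^k)
  nprobes_all <- integer(4L^k)
  summary_all[agg$code] <- agg$summary
  nprobes_all[agg$code] <- agg$n_probes
  scored <- !is.na(summary_all)
  z <- rep(NA_real_, 4L^k)
  if (any(scored)) {
    mu <- mean(summary_all[scored]); sdev <- sd(summary_all[scored])
    z[scored] <- if (is.na(sdev) || sdev == 0) 0 else (summary_all[scored] - mu) / sdev
  }
  out <- data.frame(kmer = .int_to_kmer(seq_len(4L^k)), count = occ,
                    n_probes = nprobes_all, summary = summary_all, z = z,
                    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$z), -Inf, out$z), out$kmer), ]
  rownames(out) <- NULL
  class(out) <- c("kmer_table", "data.frame")
  out
}

#' Assemble a consensus motif from top-scoring 7-mers
#'
#' Takes the `top_n` 7-mers by Z-score, aligns each to the top 7-mer by
#' the ungapped offset (within `max_offset`) maximising positional
#' agreement (ties: smaller absolute offset, then the left-shifted one),
#' stacks them into a Z-weighted position-frequency matrix (negative
#' weights floored at 0), and reduces to IUPAC by including at each
#' position every base with weighted frequency >= 0.25; uncovered columns
#' render as N and flanking all-N columns are trimmed. A 7-mer with no
#' overlap at any allowed offset is dropped with a warning.
#'
#' @param kmer_table a [kmer_zscores()] result.
#' @param top_n number of top 7-mers to stack (default 10; `top_n = 1`
#'   returns the top 7-mer verbatim).
#' @param max_offset maximum absolute alignment offset (default 3).
#' @return list of class `assembled_motif`: `motif` (`iupac_motif`), `pwm`
#'   (4 x width), `alignment` (data.frame: kmer, z, offset).
#' @export
assemble_motif <- function(kmer_table, top_n = 10L, max_offset = 3L) {
  scored <- kmer_table[!is.na(kmer_table$z), ]
  if (nrow(scored) == 0L) stop_fmt("no scored 7-mers")
  top <- head(scored[order(-scored$z, scored$kmer), ], top_n)
  k <- nchar(top$kmer[1])
  # best ungapped alignment of kmer b onto kmer a: c(agree, offset)
  best_align <- function(a, b) {
    best <- c(agree = -1L, off = 0L)
    for (off in seq(-max_offset, max_offset)) {
      js <- seq_len(k)
      ok <- js + off >= 1L & js + off <= k
      if (!any(ok)) next
      agree <- sum(substring(b, js[ok], js[ok]) ==
                     substring(a, js[ok] + off, js[ok] + off))
      better <- agree > best["agree"] ||
        (agree == best["agree"] && abs(off) < abs(best["off"]))
      if (better) best <- c(agree = agree, off = off)
    }
    best
  }
  # reference = the medoid: the top 7-mer most consistent (z-weighted
  # positional agreement) with the rest, so one spuriously high-z outlier
  # cannot anchor the alignment; ties favour the higher-z 7-mer
  wz <- pmax(top$z, 0)
  consist <- vapply(seq_len(nrow(top)), function(i) {
    sum(vapply(seq_len(nrow(top))[-i], function(j) {
      wz[j] * best_align(top$kmer[i], top$kmer[j])["agree"]
    }, numeric(1)))
  }, numeric(1))
  if (nrow(top) == 1L) consist <- 0
  ref_i <- order(-consist, -top$z, top$kmer)[1]
  ref <- top$kmer[ref_i]
  offsets <- integer(nrow(top)); keep <- rep(TRUE, nrow(top))
  for (i in seq_len(nrow(top))) {
    if (i == ref_i) next
    best <- best_align(ref, top$kmer[i])
    if (best["agree"] < 0L) {
      warning(sprintf("7-mer %s has no overlap with %s at |offset| <= %d; dropped",
                      top$kmer[i], ref, max_offset))
      keep[i] <- FALSE
    } else {
      offsets[i] <- best["off"]
    }
  }
  top <- top[keep, ]; offsets <- offsets[keep]
  w <- pmax(top$z, 0)
  if (all(w == 0)) w <- rep(1, length(w))
  lo <- min(offsets) ; hi <- max(offsets) + k - 1L
  width <- hi - lo + 1L
  counts <- matrix(0, nrow = 4L, ncol = width, dimnames = list(VALID_RNA, NULL))
  for (i in seq_len(nrow(top))) {
    cols <- offsets[i] - lo + seq_len(k)
    bases <- .encode_rna(top$kmer[i])
    for (j in seq_len(k)) counts[bases[j], cols[j]] <- counts[bases[j], cols[j]] + w[i]
  }
  tot <- colSums(counts)
  freq <- sweep(counts, 2, pmax(tot, .Machine$double.eps), "/")
  letters <- vapply(seq_len(width), function(j) {
    if (tot[j] == 0) return("N")
    inc <- VALID_RNA[freq[, j] >= 0.25]
    if (length(inc) == 0L) inc <- VALID_RNA[which.max(freq[, j])]
    key <- paste(sort(inc), collapse = "")
    names(which(vapply(IUPAC_RNA, function(b) paste(sort(b), collapse = "") == key,
                       logical(1))))[1]
  }, character(1))
  non_n <- which(letters != "N")
  if (length(non_n) == 0L) stop_fmt("assembled motif is all-N")
  rng <- non_n[1]:non_n[length(non_n)]
  structure(list(motif = iupac_motif(paste(letters[rng], collapse = "")),
                 pwm = freq[, rng, drop = FALSE],
                 alignment = data.frame(kmer = top$kmer, z = top$z,
                                        offset = offsets, stringsAsFactors = FALSE)),
            class = "assembled_motif")
}

#' @export
print.assembled_motif <- function(x, ...) {
  cat(sprintf("<assembled_motif %s from %d aligned 7-mers>\n",
              motif_string(x$motif), nrow(x$alignment)))
  invisible(x)
}

#' k-mer coverage of a probe pool
#'
#' Occurrence counts (overlapping) of every k-mer across the pool, with
#' min/median/max and an optional under-coverage flag list.
#'
#' @param pool probe pool data.frame.
#' @param k k-mer width (3 to 9).
#' @param floor optional minimum acceptable count; k-mers below it are
#'   listed.
#' @return list: `k`, `min`, `median`, `max`, `counts` (named integer,
#'   4^k entries), `below_floor` (character, when `floor` given).
#' @export
pool_coverage_report <- function(pool, k = 7L, floor = NULL) {
  if (k < 3L || k > 9L) stop_fmt("k must lie in [3, 9]")
  seqs <- gsub("T", "U", toupper(pool$sequence), fixed = TRUE)
  counts <- tabulate(unlist(lapply(seqs, .kmer_codes, k = k)), nbins = 4L^k)
  names(counts) <- .int_to_kmer(seq_len(4L^k), w = k)
  out <- list(k = k, min = min(counts), median = median(counts),
              max = max(counts), counts = counts)
  if (!is.null(floor)) out$below_floor <- names(counts)[counts < floor]
  out
}
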