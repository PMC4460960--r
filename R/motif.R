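## Accessibility-weighted IUPAC motif representation, scanning, AUROC
## evaluation and seeded greedy discriminative motif discovery.

IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"))

IUPAC_LETTERS <- names(IUPAC_RNA)

#' Degenerate RNA motif
#'
#' @param letters IUPAC string (RNA alphabet; `T` accepted and converted),
#'   width >= 4.
#' @return Object of class `iupac_motif` with fields `letters` (character
#'   vector) and `width`.
#' @export
iupac_motif <- function(letters) {
  if (inherits(letters, "iupac_motif")) return(letters)
  s <- toupper(paste(letters, collapse = ""))
  s <- gsub("T", "U", s, fixed = TRUE)
  lt <- strsplit(s, "")[[1]]
  if (length(lt) < 4L) stop_fmt("motif must have width >= 4 (got '%s')", s)
  bad <- setdiff(lt, IUPAC_LETTERS)
  if (length(bad) > 0L) stop_fmt("invalid IUPAC letter(s): %s", paste(bad, collapse = ", "))
  structure(list(letters = lt, width = length(lt)), class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat(sprintf("<iupac_motif %s (width %d)>\n", motif_string(x), x$width))
  invisible(x)
}

#' Motif as a single string
#' @param motif an `iupac_motif`.
#' @return Character scalar.
#' @export
motif_string <- function(motif) paste(motif$letters, collapse = "")

#' Number of degenerate letters in a motif
#' @param motif an `iupac_motif`.
#' @return Integer count of positions allowing more than one base.
#' @export
motif_degeneracy <- function(motif) {
  sum(vapply(motif$letters, function(l) length(IUPAC_RNA[[l]]), integer(1)) > 1L)
}

#' Minimal-degeneracy core of a motif
#'
#' The longest contiguous run of single-base (non-degenerate) letters;
#' ties are broken in favour of the leftmost run.
#'
#' @param motif an `iupac_motif` (or IUPAC string).
#' @return Character scalar (possibly empty).
#' @export
motif_core <- function(motif) {
  motif <- iupac_motif(motif)
  hard <- vapply(motif$letters, function(l) length(IUPAC_RNA[[l]]) == 1L, logical(1))
  best <- c(0L, 0L)  # start, length
  i <- 1L
  while (i <= length(hard)) {
    if (hard[i]) {
      j <- i
      while (j < length(hard) && hard[j + 1L]) j <- j + 1L
      if (j - i + 1L > best[2]) best <- c(i, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (best[2] == 0L) return("")
  paste(motif$letters[best[1]:(best[1] + best[2] - 1L)], collapse = "")
}

#' Position frequency matrix of a motif
#'
#' Uniform frequencies over the compatible bases at each position; intended
#' for logo rendering only.
#'
#' @param motif an `iupac_motif`.
#' @return 4 x width numeric matrix with rownames A, C, G, U.
#' @export
motif_pwm <- function(motif) {
  motif <- iupac_motif(motif)
  pwm <- vapply(motif$letters, function(l) {
    v <- as.numeric(VALID_RNA %in% IUPAC_RNA[[l]])
    v / sum(v)
  }, numeric(4))
  rownames(pwm) <- VALID_RNA
  colnames(pwm) <- NULL
  pwm
}

#' Are two IUPAC motifs position-wise compatible?
#'
#' Compatible means the allowed base sets intersect at every aligned
#' position (both motifs must have equal width).
#'
#' @param a,b `iupac_motif`s or IUPAC strings of equal width.
#' @return Logical scalar.
#' @export
iupac_compatible <- function(a, b) {
  a <- iupac_motif(a); b <- iupac_motif(b)
  if (a$width != b$width) stop_fmt("motif widths differ (%d vs %d)", a$width, b$width)
  all(mapply(function(x, y) length(intersect(IUPAC_RNA[[x]], IUPAC_RNA[[y]])) > 0L,
             a$letters, b$letters))
}

## integer encoding of an RNA string (A=1 C=2 G=3 U=4)
.encode_rna <- function(s) {
  v <- match(strsplit(s, "")[[1]], VALID_RNA)
  if (anyNA(v)) stop_fmt("sequence contains non-ACGU characters")
  v
}

## all IUPAC-compatible start positions of `letters` in integer sequence
.match_starts <- function(seqint, letters) {
  w <- length(letters)
  n <- length(seqint)
  if (n < w) return(integer(0))
  m <- rep(TRUE, n - w + 1L)
  for (j in seq_len(w)) {
    allowed <- VALID_RNA %in% IUPAC_RNA[[letters[j]]]
    m <- m & allowed[seqint[j:(n - w + j)]]
  }
  which(m)
}

#' Scan a transcript for accessibility-annotated motif matches
#'
#' Reports a hit at every start where the subsequence is IUPAC-compatible
#' with the motif (overlapping hits included). Each hit carries the
#' accessibility of the window ending at its last position: the track
#' entry at `start + width - 1`. Undefined entries (leading positions or
#' `NA` in the track) are treated as 0 and flagged.
#'
#' @param tx a `transcript_record`.
#' @param motif an `iupac_motif` or IUPAC string.
#' @param track an `accessibility_track` for the transcript (or `NULL` for
#'   constant accessibility 1, i.e. unweighted match counting).
#' @param region `"whole"` (default), `"utr5"`, `"orf"` or `"utr3"`; hits
#'   must lie entirely inside the region.
#' @return data.frame with columns `transcript_id`, `start`, `match`,
#'   `accessibility`, `accessibility_defined`.
#' @export
scan_motif <- function(tx, motif, track = NULL,
                       region = c("whole", "utr5", "orf", "utr3")) {
  region <- match.arg(region)
  motif <- iupac_motif(motif)
  L <- nchar(tx$sequence)
  if (!is.null(track) && length(track$p) != L) {
    stop_fmt("track length (%d) does not match transcript %s length (%d)",
             length(track$p), tx$transcript_id, L)
  }
  starts <- .match_starts(.encode_rna(tx$sequence), motif$letters)
  if (region != "whole") {
    sp <- region_span(tx, region)
    if (is.null(sp)) {
      starts <- integer(0)
    } else {
      starts <- starts[starts >= sp[1] & starts + motif$width - 1L <= sp[2]]
    }
  }
  ends <- starts + motif$width - 1L
  if (is.null(track)) {
    acc <- rep(1, length(starts)); defined <- rep(TRUE, length(starts))
  } else {
    acc <- track$p[ends]
    defined <- !is.na(acc)
    acc[!defined] <- 0
  }
  data.frame(transcript_id = rep(tx$transcript_id, length(starts)),
             start = starts,
             match = if (length(starts) > 0L) substring(tx$sequence, starts, ends) else character(0),
             accessibility = acc,
             accessibility_defined = defined,
             stringsAsFactors = FALSE)
}

#' Accessibility-weighted transcript motif score
#'
#' The sum of match accessibilities over all hits of the motif in the
#' transcript (region-restricted when requested); a transcript without a
#' match scores 0.
#'
#' @inheritParams scan_motif
#' @return Non-negative numeric scalar.
#' @export
transcript_score <- function(tx, motif, track = NULL,
                             region = c("whole", "utr5", "orf", "utr3")) {
  sum(scan_motif(tx, motif, track, region)$accessibility)
}

#' Fallback accessibility model
#'
#' Fills a track without RNAplfold output: `constant` mode assigns the
#' same probability everywhere; `gc_heuristic` assigns lower accessibility
#' to windows in GC-rich 80-nt neighbourhoods via the fixed monotone map
#' `0.9 - 0.8 * gc` (gc = local G+C fraction), reflecting the tendency of
#' GC-rich RNA to fold more stably.
#'
#' @param tx a `transcript_record`.
#' @param U site width.
#' @param mode `"constant"` or `"gc_heuristic"`.
#' @param c constant probability in `[0,1]` (constant mode).
#' @param window neighbourhood width for the GC heuristic (default 80 nt).
#' @return An `accessibility_track`.
#' @export
accessibility_fallback <- function(tx, U, mode = c("constant", "gc_heuristic"),
                                   c = 0.5, window = 80L) {
  mode <- match.arg(mode)
  L <- nchar(tx$sequence)
  if (mode == "constant") {
    if (c < 0 || c > 1) stop_fmt("constant accessibility must lie in [0,1]")
    return(accessibility_track(tx$transcript_id, U, rep(c, L)))
  }
  seqint <- .encode_rna(tx$sequence)
  isgc <- as.numeric(seqint %in% c(2L, 3L))
  half <- window %/% 2L
  cs <- cumsum(c(0, isgc))
  p <- vapply(seq_len(L), function(i) {
    lo <- max(1L, i - half); hi <- min(L, i + half)
    gc <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    0.9 - 0.8 * gc
  }, numeric(1))
  accessibility_track(tx$transcript_id, U, p)
}

## ---------------------------------------------------------------------------
## AUROC
## ---------------------------------------------------------------------------

## rank-sum AUROC (midrank ties), no p-value
.auroc_value <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' AUROC with Wilcoxon-Mann-Whitney significance
#'
#' The probability that a randomly chosen positive score exceeds a
#' randomly chosen negative score, ties counted one half
#' (`auroc = U / (n_pos * n_neg)` with midranks). The two-sided p-value is
#' computed by exact enumeration of all labelings when
#' `n_pos + n_neg <= 12` (correct under ties) and by the tie-corrected
#' normal approximation otherwise.
#'
#' @param pos,neg numeric score vectors (both non-empty).
#' @return list of class `auroc_result`: `auroc`, `U`, `p_value`, `n_pos`,
#'   `n_neg`.
#' @export
auroc <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L) stop_fmt("both score sets must be non-empty")
  np <- length(pos); nn <- length(neg)
  a <- .auroc_value(pos, neg)
  U <- a * np * nn
  mu <- np * nn / 2
  if (np + nn <= 12L) {
    comb <- combn(np + nn, np)
    allsc <- c(pos, neg)
    dev_obs <- abs(U - mu)
    devs <- apply(comb, 2, function(idx) {
      abs(.auroc_value(allsc[idx], allsc[-idx]) * np * nn - mu)
    })
    p <- mean(devs >= dev_obs - 1e-12)
  } else {
    allsc <- c(pos, neg)
    nt <- table(allsc)
    n <- np + nn
    tie_term <- sum(nt^3 - nt) / (n * (n - 1))
    sigma2 <- (np * nn / 12) * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(list(auroc = a, U = U, p_value = p, n_pos = np, n_neg = nn),
            class = "auroc_result")
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("<auroc %.4f (n_pos=%d, n_neg=%d), two-sided WMW p=%.3g>\n",
              x$auroc, x$n_pos, x$n_neg, x$p_value))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Motif corpus: concatenated encoding of a transcript set for fast
## repeated scoring during discovery
## ---------------------------------------------------------------------------

#' Precompute a scoring corpus over a transcript set
#'
#' Concatenates all sequences into one integer encoding with per-position
#' transcript, region and accessibility annotations, and indexes every
#' exact 7-mer occurrence with its accessibility weight. Repeatedly scored
#' motifs are memoised, so cross-validation folds over the same corpus
#' reuse earlier scans.
#'
#' @param transcripts a `transcript_set` (named list of
#'   `transcript_record`s).
#' @param tracks named list of `accessibility_track`s (names = gene ids),
#'   or `NULL` for constant accessibility 1.
#' @return Object of class `motif_corpus`.
#' @export
motif_corpus <- function(transcripts, tracks = NULL) {
  genes <- names(transcripts)
  lens <- vapply(transcripts, function(tx) nchar(tx$sequence), integer(1))
  offs <- cumsum(c(0L, lens[-length(lens)]))
  names(offs) <- genes
  N <- sum(lens)
  seqint <- integer(N); acc <- rep(NA_real_, N); regc <- integer(N); txi <- integer(N)
  for (i in seq_along(genes)) {
    tx <- transcripts[[i]]
    idx <- offs[i] + seq_len(lens[i])
    seqint[idx] <- .encode_rna(tx$sequence)
    txi[idx] <- i
    if (!is.null(tx$utr5)) regc[idx[tx$utr5[1]:tx$utr5[2]]] <- 1L
    if (!is.null(tx$orf)) regc[idx[tx$orf[1]:tx$orf[2]]] <- 2L
    if (!is.null(tx$utr3)) regc[idx[tx$utr3[1]:tx$utr3[2]]] <- 3L
    if (!is.null(tracks)) {
      tr <- tracks[[genes[i]]]
      if (!is.null(tr)) {
        if (length(tr$p) != lens[i]) {
          stop_fmt("track length mismatch for %s", genes[i])
        }
        acc[idx] <- tr$p
      }
    } else {
      acc[idx] <- 1
    }
  }
  ind <- lapply(1:4, function(b) seqint == b)
  corpus <- list(genes = genes, n_genes = length(genes), lens = lens,
                 offsets = offs, N = N, seqint = seqint, ind = ind,
                 acc = acc, region = regc, tx_of = txi,
                 memo = new.env(parent = emptyenv()),
                 kmer = NULL)
  class(corpus) <- "motif_corpus"
  corpus$kmer <- .index_7mers(corpus)
  corpus
}

#' @export
print.motif_corpus <- function(x, ...) {
  cat(sprintf("<motif_corpus: %d transcripts, %d nt total>\n", x$n_genes, x$N))
  invisible(x)
}

## Sparse per-transcript accessibility-weighted scores for all exact
## 7-mers: list (by 7-mer code 1..4^7) of list(tx = integer, sc = numeric),
## plus per-code positive-score transcript counts.
.index_7mers <- function(corpus) {
  w <- 7L
  N <- corpus$N
  if (N < w) return(list(by_code = list(), w = w))
  nstart <- N - w + 1L
  valid <- corpus$tx_of[seq_len(nstart)] == corpus$tx_of[seq_len(nstart) + w - 1L]
  code <- integer(nstart)
  for (j in seq_len(w)) {
    code <- code * 4L + (corpus$seqint[j:(N - w + j)] - 1L)
  }
  code <- code + 1L
  s <- which(valid)
  a <- corpus$acc[s + w - 1L]
  a[is.na(a)] <- 0
  keep <- a > 0
  dt <- data.table::data.table(code = code[s][keep], tx = corpus$tx_of[s][keep],
                               a = a[keep])
  agg <- dt[, list(sc = sum(a)), by = c("code", "tx")]
  agg <- as.data.frame(agg[agg$sc > 0, ])
  by_code <- split(agg[, c("tx", "sc")], agg$code)
  list(by_code = by_code, w = w)
}

## score vector (length n_genes) for a motif over the corpus, memoised
.corpus_scores <- function(corpus, letters, region = "whole") {
  key <- paste(paste(letters, collapse = ""), region, sep = "|")
  hit <- corpus$memo[[key]]
  if (!is.null(hit)) return(hit)
  w <- length(letters)
  N <- corpus$N
  m <- rep(TRUE, N - w + 1L)
  for (j in seq_len(w)) {
    allowed <- VALID_RNA %in% IUPAC_RNA[[letters[j]]]
    if (all(allowed)) next
    v <- if (sum(allowed) == 1L) {
      corpus$ind[[which(allowed)]]
    } else {
      Reduce(`|`, corpus$ind[which(allowed)])
    }
    m <- m & v[j:(N - w + j)]
  }
  scores <- .scores_from_match(corpus, m, w, region)
  corpus$memo[[key]] <- scores
  scores
}

.scores_from_match <- function(corpus, m, w, region) {
  nstart <- corpus$N - w + 1L
  starts <- which(m)
  ends <- starts + w - 1L
  ok <- corpus$tx_of[starts] == corpus$tx_of[ends]
  if (region != "whole") {
    rc <- match(region, c("utr5", "orf", "utr3"))
    ok <- ok & corpus$region[starts] == rc & corpus$region[ends] == rc
  }
  starts <- starts[ok]; ends <- ends[ok]
  scores <- numeric(corpus$n_genes)
  if (length(starts) > 0L) {
    a <- corpus$acc[ends]
    a[is.na(a)] <- 0
    agg <- rowsum(a, corpus$tx_of[starts])
    scores[as.integer(rownames(agg))] <- agg[, 1]
  }
  names(scores) <- corpus$genes
  scores
}

#' Score every corpus transcript under a motif
#'
#' @param corpus a [motif_corpus()].
#' @param motif an `iupac_motif` or IUPAC string.
#' @param region `"whole"`, `"utr5"`, `"orf"` or `"utr3"`.
#' @return Named numeric vector of accessibility-weighted scores.
#' @export
score_transcripts <- function(corpus, motif,
                              region = c("whole", "utr5", "orf", "utr3")) {
  region <- match.arg(region)
  motif <- iupac_motif(motif)
  .corpus_scores(corpus, motif$letters, region)
}

## ---------------------------------------------------------------------------
## Discovery
## ---------------------------------------------------------------------------

#' Motif discovery parameters
#'
#' @param n_seeds number of top-ranked exact 7-mers used to seed greedy
#'   refinement (default 10).
#' @param max_width maximum motif width after flank extension (default 9).
#' @param min_genes minimum size of each class (default 20).
#' @param max_sweeps cap on greedy refinement sweeps (default 20; sweeps
#'   normally converge in 2-4).
#' @param n_repeats,n_folds cross-validation layout (default 3 x 10).
#' @param seed RNG seed for the cross-validation splits.
#' @return list of class `motif_params`.
#' @export
motif_params <- function(n_seeds = 10L, max_width = 9L, min_genes = 20L,
                         max_sweeps = 20L, n_repeats = 3L, n_folds = 10L,
                         seed = 1L) {
  structure(list(n_seeds = as.integer(n_seeds), max_width = as.integer(max_width),
                 min_genes = as.integer(min_genes), max_sweeps = as.integer(max_sweeps),
                 n_repeats = as.integer(n_repeats), n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "motif_params")
}

.int_to_kmer <- function(code, w = 7L) {
  code <- code - 1L
  cols <- lapply(seq_len(w), function(j) VALID_RNA[((code %/% 4L^(w - j)) %% 4L) + 1L])
  do.call(paste0, cols)
}

## rank all indexed 7-mers by training AUROC of their accessibility
## weighted scores; returns data.frame(code, kmer, auroc, n_pos_matched)
.rank_seed_kmers <- function(corpus, pos_idx, neg_idx) {
  P <- length(pos_idx); N <- length(neg_idx)
  is_pos <- logical(corpus$n_genes); is_pos[pos_idx] <- TRUE
  is_neg <- logical(corpus$n_genes); is_neg[neg_idx] <- TRUE
  by_code <- corpus$kmer$by_code
  codes <- as.integer(names(by_code))
  au <- numeric(length(codes)); npm <- integer(length(codes))
  for (i in seq_along(codes)) {
    e <- by_code[[i]]
    inp <- is_pos[e$tx]; inn <- is_neg[e$tx]
    p_nz <- e$sc[inp]; n_nz <- e$sc[inn]
    np_nz <- length(p_nz); nn_nz <- length(n_nz)
    P0 <- P - np_nz; N0 <- N - nn_nz
    wins <- np_nz * N0 + 0.5 * P0 * N0
    if (np_nz > 0L && nn_nz > 0L) {
      r <- rank(c(p_nz, n_nz))
      wins <- wins + sum(r[seq_len(np_nz)]) - np_nz * (np_nz + 1) / 2
    }
    au[i] <- wins / (P * N)
    npm[i] <- np_nz
  }
  df <- data.frame(code = codes, kmer = .int_to_kmer(codes), auroc = au,
                   n_pos_matched = npm, stringsAsFactors = FALSE)
  df[order(-df$auroc, -df$n_pos_matched, df$kmer), ]
}

## training AUROC of a letter vector over corpus subsets
.train_auroc <- function(corpus, letters, pos_idx, neg_idx) {
  sc <- .corpus_scores(corpus, letters, "whole")
  .auroc_value(sc[pos_idx], sc[neg_idx])
}

## shifted indicator vector for one motif position: does corpus position
## s + j - 1 carry a base allowed by `letter`? (length N - w + 1)
.shifted_ind <- function(corpus, letter, j, w) {
  allowed <- VALID_RNA %in% IUPAC_RNA[[letter]]
  N <- corpus$N
  if (all(allowed)) return(rep(TRUE, N - w + 1L))
  v <- if (sum(allowed) == 1L) {
    corpus$ind[[which(allowed)]]
  } else {
    Reduce(`|`, corpus$ind[which(allowed)])
  }
  v[j:(N - w + j)]
}

## scores for a substitution candidate, memoised; `base` is the AND of the
## indicator vectors of all other positions
.cand_scores <- function(corpus, cand_letters, base, letter, j, w) {
  key <- paste(paste(cand_letters, collapse = ""), "whole", sep = "|")
  hit <- corpus$memo[[key]]
  if (!is.null(hit)) return(hit)
  m <- base & .shifted_ind(corpus, letter, j, w)
  scores <- .scores_from_match(corpus, m, w, "whole")
  corpus$memo[[key]] <- scores
  scores
}

## one greedy refinement from a seed 7-mer: sweep positions (with single
## flank growth on either side up to max_width), keeping the best
## strictly-improving IUPAC substitution at each position, until a full
## sweep changes nothing
.refine_seed <- function(corpus, seed_kmer, pos_idx, neg_idx, params) {
  letters <- strsplit(seed_kmer, "")[[1]]
  best_au <- .train_auroc(corpus, letters, pos_idx, neg_idx)
  for (sweep in seq_len(params$max_sweeps)) {
    changed <- FALSE
    restart <- FALSE
    w <- length(letters)
    # flank growth candidates (full scans, memoised)
    for (pos in c(0L, w + 1L)) {
      if (length(letters) >= params$max_width) break
      cand_best <- NULL; cand_au <- best_au
      for (l in IUPAC_LETTERS) {
        cand <- if (pos == 0L) c(l, letters) else c(letters, l)
        sc <- .corpus_scores(corpus, cand, "whole")
        au <- .auroc_value(sc[pos_idx], sc[neg_idx])
        if (au > cand_au + 1e-12) { cand_au <- au; cand_best <- cand }
      }
      if (!is.null(cand_best)) {
        letters <- cand_best; best_au <- cand_au
        changed <- TRUE; restart <- TRUE
        break
      }
    }
    if (restart) next  # width changed: rebuild indicators on next sweep
    # per-position substitutions with incremental prefix/suffix ANDs
    V <- lapply(seq_len(w), function(j) .shifted_ind(corpus, letters[j], j, w))
    for (j in seq_len(w)) {
      prefix <- if (j == 1L) NULL else Reduce(`&`, V[seq_len(j - 1L)])
      suffix <- if (j == w) NULL else Reduce(`&`, V[(j + 1L):w])
      base <- if (is.null(prefix)) suffix else if (is.null(suffix)) prefix else prefix & suffix
      cand_best <- NULL; cand_au <- best_au; cand_letter <- NULL
      for (l in IUPAC_LETTERS) {
        if (l == letters[j]) next
        cand <- replace(letters, j, l)
        sc <- .cand_scores(corpus, cand, base, l, j, w)
        au <- .auroc_value(sc[pos_idx], sc[neg_idx])
        if (au > cand_au + 1e-12) { cand_au <- au; cand_best <- cand; cand_letter <- l }
      }
      if (!is.null(cand_best)) {
        letters <- cand_best; best_au <- cand_au; changed <- TRUE
        V[[j]] <- .shifted_ind(corpus, cand_letter, j, w)
      }
    }
    if (!changed) break
  }
  list(letters = letters, auroc = best_au)
}

#' Discriminative de novo motif discovery
#'
#' Finds the IUPAC motif whose accessibility-weighted transcript score
#' best separates positive from negative transcripts (training AUROC).
#' The search (1) ranks all exact 7-mers by the AUROC of their scores,
#' (2) takes the top `n_seeds` as seeds, (3) greedily refines each seed by
#' sweeping positions (including up to one flanking position on each side,
#' to `max_width`) and keeping any IUPAC substitution that strictly
#' increases the training AUROC until a full sweep makes no change, and
#' (4) returns the refined motif with the highest training AUROC (ties:
#' fewer degenerate letters, then lexicographic). The procedure is
#' deterministic.
#'
#' @param corpus a [motif_corpus()] over all transcripts involved.
#' @param positives,negatives disjoint character vectors of gene ids
#'   present in the corpus (each at least `params$min_genes` long).
#' @param params a [motif_params()].
#' @return list of class `motif_discovery`: `motif` (`iupac_motif`),
#'   `training_auroc`, `seed` (the seeding 7-mer), `seed_table` (top-seed
#'   ranking with refined AUROCs).
#' @export
discover_motif <- function(corpus, positives, negatives, params = motif_params()) {
  overlap <- intersect(positives, negatives)
  if (length(overlap) > 0L) stop_fmt("positive/negative sets overlap (%d gene(s))",
                                     length(overlap))
  if (length(positives) < params$min_genes || length(negatives) < params$min_genes) {
    stop_fmt("need at least %d genes per class (got %d/%d)",
             params$min_genes, length(positives), length(negatives))
  }
  pos_idx <- match(positives, corpus$genes)
  neg_idx <- match(negatives, corpus$genes)
  if (anyNA(pos_idx) || anyNA(neg_idx)) stop_fmt("gene id(s) absent from corpus")

  ranking <- .rank_seed_kmers(corpus, pos_idx, neg_idx)
  seeds <- head(ranking, params$n_seeds)
  if (nrow(seeds) == 0L) stop_fmt("no 7-mer has a nonzero score in the corpus")

  refined <- lapply(seeds$kmer, .refine_seed, corpus = corpus,
                    pos_idx = pos_idx, neg_idx = neg_idx, params = params)
  strs <- vapply(refined, function(r) paste(r$letters, collapse = ""), character(1))
  aus <- vapply(refined, function(r) r$auroc, numeric(1))
  degs <- vapply(strs, function(s) motif_degeneracy(iupac_motif(s)), integer(1))
  pick <- order(-aus, degs, strs)[1]
  structure(list(motif = iupac_motif(strs[pick]),
                 training_auroc = aus[pick],
                 seed = seeds$kmer[pick],
                 seed_table = data.frame(seeds, refined = strs,
                                         refined_auroc = aus,
                                         stringsAsFactors = FALSE)),
            class = "motif_discovery")
}

#' @export
print.motif_discovery <- function(x, ...) {
  cat(sprintf("<motif_discovery: %s (training AUROC %.3f, seed %s)>\n",
              motif_string(x$motif), x$training_auroc, x$seed))
  invisible(x)
}

#' Cross-validated motif discovery
#'
#' Repeats a stratified 10-fold split `n_repeats` times (default 3 x 10):
#' positives and negatives are independently shuffled and dealt into
#' `n_folds` near-equal bins, a motif is discovered on each training split
#' and its AUROC measured on the held-out bin, yielding
#' `n_repeats * n_folds` held-out AUROCs (30 under the defaults).
#'
#' @inheritParams discover_motif
#' @return list of class `cv_result`: `aurocs` (numeric, length
#'   `n_repeats * n_folds`), `mean_auroc`, `folds` (data.frame with repeat,
#'   fold, motif, training and held-out AUROC), `seed`.
#' @export
cross_validate <- function(corpus, positives, negatives, params = motif_params()) {
  nf <- params$n_folds
  if (length(positives) < nf || length(negatives) < nf) {
    stop_fmt("class too small for %d bins (%d/%d genes); use fewer bins",
             nf, length(positives), length(negatives))
  }
  rows <- list()
  for (rep_i in seq_len(params$n_repeats)) {
    set.seed(params$seed + rep_i - 1L)
    pf <- sample(rep_len(seq_len(nf), length(positives)))
    nfold <- sample(rep_len(seq_len(nf), length(negatives)))
    for (fold in seq_len(nf)) {
      tr_pos <- positives[pf != fold]; te_pos <- positives[pf == fold]
      tr_neg <- negatives[nfold != fold]; te_neg <- negatives[nfold == fold]
      p <- params; p$min_genes <- min(p$min_genes, length(tr_pos), length(tr_neg))
      disc <- discover_motif(corpus, tr_pos, tr_neg, p)
      sc <- score_transcripts(corpus, disc$motif)
      held <- .auroc_value(sc[match(te_pos, corpus$genes)],
                           sc[match(te_neg, corpus$genes)])
      rows[[length(rows) + 1L]] <-
        data.frame(rep = rep_i, fold = fold, motif = motif_string(disc$motif),
                   training_auroc = disc$training_auroc, heldout_auroc = held,
                   stringsAsFactors = FALSE)
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(aurocs = folds$heldout_auroc,
                 mean_auroc = mean(folds$heldout_auroc),
                 folds = folds, seed = params$seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d held-out AUROCs, mean %.3f>\n",
              length(x$aurocs), x$mean_auroc))
  invisible(x)
}

#' Per-region motif enrichment
#'
#' AUROC of the region-restricted accessibility-weighted score of
#' `gene_list` versus `control_list`, for each of 5'UTR, ORF, 3'UTR and
#' the whole transcript. Genes lacking the region annotation are excluded
#' from that region's comparison (their count is reported); a warning is
#' raised when more than half of either list lacks a region.
#' Bonferroni-corrected p-values are reported alongside the raw WMW p
#' (default correction count: the four regions tested).
#'
#' @param gene_list,control_list disjoint character vectors of gene ids.
#' @param motif an `iupac_motif` or IUPAC string.
#' @param corpus a [motif_corpus()].
#' @param m_tests Bonferroni correction count (default 4; multiply by the
#'   number of gene lists when several are tested in one run).
#' @return data.frame with one row per region: `region`, `auroc`,
#'   `p_value`, `p_bonferroni`, `n_pos`, `n_neg`.
#' @export
region_enrichment <- function(gene_list, control_list, motif, corpus,
                              m_tests = 4L) {
  if (length(intersect(gene_list, control_list)) > 0L) {
    stop_fmt("gene list and control list overlap")
  }
  motif <- iupac_motif(motif)
  has_region <- function(idx, rc) {
    vapply(idx, function(i) {
      span <- corpus$offsets[i] + seq_len(corpus$lens[i])
      any(corpus$region[span] == rc)
    }, logical(1))
  }
  pos_idx <- match(gene_list, corpus$genes)
  neg_idx <- match(control_list, corpus$genes)
  if (anyNA(pos_idx) || anyNA(neg_idx)) stop_fmt("gene id(s) absent from corpus")
  out <- list()
  for (region in c("utr5", "orf", "utr3", "whole")) {
    if (region == "whole") {
      pi <- pos_idx; ni <- neg_idx
    } else {
      rc <- match(region, c("utr5", "orf", "utr3"))
      pkeep <- has_region(pos_idx, rc); nkeep <- has_region(neg_idx, rc)
      if (mean(pkeep) < 0.5 || mean(nkeep) < 0.5) {
        warning(sprintf("region %s absent for >50%% of genes (pos %d/%d, neg %d/%d kept)",
                        region, sum(pkeep), length(pkeep), sum(nkeep), length(nkeep)))
      }
      pi <- pos_idx[pkeep]; ni <- neg_idx[nkeep]
    }
    if (length(pi) == 0L || length(ni) == 0L) {
      out[[region]] <- data.frame(region = region, auroc = NA_real_,
                                  p_value = NA_real_, p_bonferroni = NA_real_,
                                  n_pos = length(pi), n_neg = length(ni))
      next
    }
    sc <- score_transcripts(corpus, motif, region)
    ar <- auroc(sc[pi], sc[ni])
    out[[region]] <- data.frame(region = region, auroc = ar$auroc,
                                p_value = ar$p_value,
                                p_bonferroni = min(1, ar$p_value * m_tests),
                                n_pos = length(pi), n_neg = length(ni))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
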