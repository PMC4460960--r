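#' @importFrom stats median sd cor quantile rnorm runif setNames complete.cases
#' @importFrom utils combn head read.delim write.table
#' @importFrom data.table data.table .N
NULL

VALID_RNA <- c("A", "C", "G", "U")

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

## ---------------------------------------------------------------------------
## TranscriptRecord
## ---------------------------------------------------------------------------

#' Construct a transcript record
#'
#' A transcript record holds one gene's representative (longest-isoform) RNA
#' sequence together with 1-based inclusive spans for its 5'UTR, ORF and
#' 3'UTR. Any span may be empty (`NULL`); non-empty spans must be disjoint,
#' ordered 5'UTR < ORF < 3'UTR, and jointly cover the full sequence. A
#' transcript with no region annotation is treated as a single unpartitioned
#' region: it can be scored whole-transcript but is excluded from per-region
#' analyses.
#'
#' @param gene_id,transcript_id identifiers (opaque strings).
#' @param sequence RNA sequence; `T` is converted to `U` on ingest.
#' @param utr5,orf,utr3 length-2 integer vectors `c(start, end)` (1-based,
#'   inclusive) or `NULL` for an empty span.
#' @return An object of class `transcript_record`.
#' @export
transcript_record <- function(gene_id, transcript_id = gene_id, sequence,
                              utr5 = NULL, orf = NULL, utr3 = NULL) {
  sequence <- toupper(sequence)
  sequence <- gsub("T", "U", sequence, fixed = TRUE)
  if (nchar(sequence) == 0L) stop_fmt("transcript %s: empty sequence", transcript_id)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), VALID_RNA)
  if (length(bad) > 0L) {
    stop_fmt("transcript %s: unknown characters in sequence: %s",
             transcript_id, paste(bad, collapse = ", "))
  }
  L <- nchar(sequence)
  spans <- list(utr5 = utr5, orf = orf, utr3 = utr3)
  spans <- spans[!vapply(spans, is.null, logical(1))]
  if (length(spans) > 0L) {
    for (nm in names(spans)) {
      sp <- as.integer(spans[[nm]])
      if (length(sp) != 2L || sp[1] < 1L || sp[2] > L || sp[1] > sp[2]) {
        stop_fmt("transcript %s: invalid %s span [%s]", transcript_id, nm,
                 paste(spans[[nm]], collapse = ","))
      }
      spans[[nm]] <- sp
    }
    ord <- do.call(rbind, spans)
    ord <- ord[order(ord[, 1]), , drop = FALSE]
    if (any(ord[-1, 1] <= ord[-nrow(ord), 2])) {
      stop_fmt("transcript %s: overlapping spans", transcript_id)
    }
    want <- intersect(c("utr5", "orf", "utr3"), names(spans))
    if (!identical(rownames(ord), want)) {
      stop_fmt("transcript %s: spans out of 5'UTR < ORF < 3'UTR order", transcript_id)
    }
    covered <- sum(ord[, 2] - ord[, 1] + 1L)
    if (covered != L || ord[1, 1] != 1L || ord[nrow(ord), 2] != L) {
      stop_fmt("transcript %s: spans do not cover [1, %d]", transcript_id, L)
    }
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 sequence = sequence,
                 utr5 = spans$utr5, orf = spans$orf, utr3 = spans$utr3),
            class = "transcript_record")
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript %s (gene %s), %d nt>\n",
              x$transcript_id, x$gene_id, nchar(x$sequence)))
  invisible(x)
}

#' Region span of a transcript
#'
#' @param tx a `transcript_record`.
#' @param region one of `"whole"`, `"utr5"`, `"orf"`, `"utr3"`.
#' @return `c(start, end)` or `NULL` when the region is absent.
#' @export
region_span <- function(tx, region = c("whole", "utr5", "orf", "utr3")) {
  region <- match.arg(region)
  if (region == "whole") return(c(1L, nchar(tx$sequence)))
  tx[[region]]
}

#' Read transcripts from FASTA plus a region table
#'
#' One record per gene is kept: when several isoforms share a `gene_id`, the
#' longest sequence wins (ties broken by transcript id). DNA is converted to
#' RNA. Region spans come from a TSV with columns `gene_id`, `transcript_id`,
#' `utr5_start`, `utr5_end`, `orf_start`, `orf_end`, `utr3_start`,
#' `utr3_end`; a 0 or `NA` start marks an empty span. Transcripts missing
#' from the region table are kept unpartitioned.
#'
#' @param fasta_path FASTA of transcript sequences, ids matching
#'   `transcript_id` in the region table.
#' @param region_table_path TSV path, or `NULL` for all-unpartitioned.
#' @return A named list of `transcript_record`s (names = gene ids), class
#'   `transcript_set`. Unmatched FASTA ids are reported in
#'   `attr(, "unmatched")` rather than guessed at.
#' @export
read_transcripts <- function(fasta_path, region_table_path = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  regions <- NULL
  if (!is.null(region_table_path)) {
    regions <- read.delim(region_table_path, stringsAsFactors = FALSE)
    need <- c("gene_id", "transcript_id", "utr5_start", "utr5_end",
              "orf_start", "orf_end", "utr3_start", "utr3_end")
    miss <- setdiff(need, names(regions))
    if (length(miss) > 0L) {
      stop_fmt("region table missing columns: %s", paste(miss, collapse = ", "))
    }
  }
  span_of <- function(row, pre) {
    s <- row[[paste0(pre, "_start")]]; e <- row[[paste0(pre, "_end")]]
    if (is.na(s) || s == 0L) NULL else c(as.integer(s), as.integer(e))
  }
  recs <- vector("list", length(seqs))
  unmatched <- character(0)
  for (i in seq_along(seqs)) {
    tid <- ids[i]
    seq_i <- as.character(seqs[[i]])
    if (is.null(regions)) {
      recs[[i]] <- transcript_record(tid, tid, seq_i)
      next
    }
    row <- regions[regions$transcript_id == tid, , drop = FALSE]
    if (nrow(row) == 0L) {
      unmatched <- c(unmatched, tid)
      recs[[i]] <- transcript_record(tid, tid, seq_i)
    } else {
      row <- row[1, ]
      recs[[i]] <- transcript_record(row$gene_id, tid, seq_i,
                                     utr5 = span_of(row, "utr5"),
                                     orf = span_of(row, "orf"),
                                     utr3 = span_of(row, "utr3"))
    }
  }
  gene <- vapply(recs, function(r) r$gene_id, character(1))
  len <- vapply(recs, function(r) nchar(r$sequence), integer(1))
  tid <- vapply(recs, function(r) r$transcript_id, character(1))
  keep <- vapply(split(seq_along(recs), gene), function(idx) {
    idx[order(-len[idx], tid[idx])][1]
  }, integer(1))
  out <- recs[keep]
  names(out) <- gene[keep]
  out <- out[order(names(out))]
  if (length(unmatched) > 0L) {
    warning(sprintf("%d FASTA id(s) absent from region table (kept unpartitioned): %s",
                    length(unmatched), paste(head(unmatched, 5), collapse = ", ")))
  }
  structure(out, class = "transcript_set", unmatched = unmatched)
}

#' Write transcripts as FASTA plus region table
#'
#' Inverse of [read_transcripts()]; the round trip is the identity.
#'
#' @param transcripts a `transcript_set`.
#' @param fasta_path,region_table_path output paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, region_table_path) {
  lines <- unlist(lapply(transcripts, function(tx) {
    c(paste0(">", tx$transcript_id), tx$sequence)
  }), use.names = FALSE)
  writeLines(lines, fasta_path)
  sp <- function(x) if (is.null(x)) c(0L, 0L) else x
  tab <- do.call(rbind, lapply(transcripts, function(tx) {
    data.frame(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
               utr5_start = sp(tx$utr5)[1], utr5_end = sp(tx$utr5)[2],
               orf_start = sp(tx$orf)[1], orf_end = sp(tx$orf)[2],
               utr3_start = sp(tx$utr3)[1], utr3_end = sp(tx$utr3)[2],
               stringsAsFactors = FALSE)
  }))
  write.table(tab, region_table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

## ---------------------------------------------------------------------------
## ExpressionMatrix
## ---------------------------------------------------------------------------

#' Construct an expression matrix with sample metadata
#'
#' @param values numeric matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids). All values must be finite and gene ids
#'   unique.
#' @param samples data.frame with columns `sample_id`, `role` (one of
#'   `RIP`, `control`, `input`, `mutant`, `wildtype`), `replicate`
#'   (integer), and optionally `timepoint`.
#' @param log2 logical flag: are the values on the log2 scale?
#' @return Object of class `expr_matrix`: list(values, samples, log2).
#' @export
expr_matrix <- function(values, samples, log2 = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) stop_fmt("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_fmt("values must carry gene ids (rownames) and sample ids (colnames)")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0L) stop_fmt("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop_fmt("non-finite value at gene %s, sample %s",
             rownames(values)[bad[1]], colnames(values)[bad[2]])
  }
  if (!all(c("sample_id", "role", "replicate") %in% names(samples))) {
    stop_fmt("sample sheet needs columns sample_id, role, replicate")
  }
  roles <- c("RIP", "control", "input", "mutant", "wildtype")
  if (!all(samples$role %in% roles)) {
    stop_fmt("unknown role(s): %s", paste(setdiff(samples$role, roles), collapse = ", "))
  }
  miss <- setdiff(colnames(values), samples$sample_id)
  if (length(miss) > 0L) stop_fmt("sample(s) missing from sheet: %s", paste(miss, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(samples$timepoint)) samples$timepoint <- NA_character_
  structure(list(values = values, samples = samples, log2 = isTRUE(log2)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix: %d genes x %d samples (%s scale)>\n",
              nrow(x$values), ncol(x$values), if (x$log2) "log2" else "linear"))
  invisible(x)
}

#' Read an expression TSV plus sample sheet
#'
#' The matrix TSV has `gene_id` as first column, one column per sample; the
#' sample sheet TSV has columns `sample_id`, `role`, `replicate` and
#' optionally `timepoint`. Non-numeric cells and duplicated gene rows are
#' rejected with coordinates.
#'
#' @param path matrix TSV path.
#' @param sample_sheet_path sample sheet TSV path.
#' @param log2 scale flag recorded on the result.
#' @return An `expr_matrix`.
#' @export
read_expression_tsv <- function(path, sample_sheet_path, log2 = TRUE) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (names(tab)[1] != "gene_id") stop_fmt("first column must be gene_id")
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(dup) > 0L) stop_fmt("duplicated gene row(s): %s", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(tab$gene_id, colnames(vals))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_fmt("non-numeric cell at gene %s, sample %s (value '%s')",
             rownames(num)[bad[1]], colnames(num)[bad[2]], vals[bad[1], bad[2]])
  }
  sheet <- read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  expr_matrix(num, sheet, log2 = log2)
}

#' Write an expression matrix and its sample sheet as TSV
#'
#' Values are written with full precision so the write/read round trip is
#' bit-exact.
#'
#' @param em an `expr_matrix`.
#' @param path,sample_sheet_path output paths.
#' @export
write_expression_tsv <- function(em, path, sample_sheet_path) {
  tab <- data.frame(gene_id = rownames(em$values),
                    apply(em$values, 2, function(col) sprintf("%.17g", col)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(em$samples, sample_sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

## ---------------------------------------------------------------------------
## AccessibilityTrack
## ---------------------------------------------------------------------------

#' Construct an accessibility track
#'
#' Entry `i` of `p` is the probability that the `U`-length window ending at
#' position `i` is entirely unpaired under a local folding model; entries
#' with `i < U` are undefined (`NA`).
#'
#' @param transcript_id identifier.
#' @param U site width (>= 1).
#' @param p numeric vector, length = transcript length, values in `[0,1]`
#'   or `NA`.
#' @return Object of class `accessibility_track`.
#' @export
accessibility_track <- function(transcript_id, U, p) {
  U <- as.integer(U)
  if (U < 1L) stop_fmt("U must be >= 1")
  if (U > 1L) p[seq_len(min(U - 1L, length(p)))] <- NA_real_
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) stop_fmt("track %s: probability outside [0,1] at position %d",
                         transcript_id, which(!ok)[1])
  structure(list(transcript_id = transcript_id, U = U, p = as.numeric(p)),
            class = "accessibility_track")
}

#' Read an RNAplfold `_lunp` unpaired-probability file
#'
#' The `_lunp` dialect: one or more comment/header lines starting with `#`,
#' then one row per transcript position; column 1 is the position, column
#' `k + 1` the probability that the `k`-length window ending at that
#' position is entirely unpaired. `NA` entries are allowed.
#'
#' @param path file path.
#' @param U window width to extract (must not exceed the available columns).
#' @param transcript_id id to record on the track (default: file base name
#'   minus `_lunp`).
#' @return An `accessibility_track`.
#' @export
read_lunp <- function(path, U, transcript_id = sub("_lunp$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_fmt("%s: no data rows", path)
  rows <- strsplit(trimws(lines), "\\s+")
  ncols <- max(lengths(rows)) - 1L
  if (U > ncols) stop_fmt("%s: requested U=%d but only %d width column(s) present",
                          path, U, ncols)
  pos <- as.integer(vapply(rows, `[`, character(1), 1L))
  val <- vapply(rows, function(r) {
    if (length(r) >= U + 1L) suppressWarnings(as.numeric(r[U + 1L])) else NA_real_
  }, numeric(1))
  p <- rep(NA_real_, max(pos))
  p[pos] <- val
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad) > 0L) stop_fmt("%s: probability outside [0,1] at position %d", path, bad[1])
  accessibility_track(transcript_id, U, p)
}

#' Write an accessibility track in the `_lunp` dialect
#'
#' Writes a single probability column at width `track$U`, padding the
#' leading undefined widths with `NA` columns so [read_lunp()] with the same
#' `U` reproduces the track.
#'
#' @param track an `accessibility_track`.
#' @param path output path.
#' @export
write_lunp <- function(track, path) {
  U <- track$U
  fmt_p <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  rows <- vapply(seq_along(track$p), function(i) {
    cells <- c(rep("NA", U - 1L), fmt_p(track$p[i]))
    paste(c(i, cells), collapse = "\t")
  }, character(1))
  writeLines(c(sprintf("#unpaired probabilities"),
               paste(c("#i$", paste0("l=", seq_len(U))), collapse = "\t"), rows), path)
  invisible(NULL)
}

## ---------------------------------------------------------------------------
## GeneSetCollection
## ---------------------------------------------------------------------------

#' Construct a gene-set collection
#'
#' @param sets named list; each element a list with `term_id`, `term_name`,
#'   `members` (character). Members are deduplicated; term ids must be
#'   unique.
#' @param background character vector of gene ids (the universe). Members
#'   are intersected with the background when one is supplied.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background = NULL) {
  ids <- vapply(sets, function(s) s$term_id, character(1))
  if (anyDuplicated(ids)) stop_fmt("duplicate term id(s): %s",
                                   paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(sets, function(s) {
    s$members <- unique(s$members)
    if (!is.null(background)) s$members <- intersect(s$members, background)
    s
  })
  names(sets) <- ids
  structure(list(sets = sets, background = background), class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Standard GMT: `term_id TAB description TAB member...`, one set per line.
#' Duplicate members within a line are stored once.
#'
#' @param path GMT path.
#' @param background optional gene universe to intersect members with.
#' @return A `gene_set_collection`. An empty file yields an empty
#'   collection with a warning.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning(sprintf("%s: empty GMT file", path))
    return(gene_set_collection(list(), background))
  }
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_fmt("%s: line %d has fewer than 3 fields", path, i)
    list(term_id = f[1], term_name = f[2], members = unique(f[-(1:2)]))
  })
  gene_set_collection(sets, background)
}

#' Write a gene-set collection as GMT
#'
#' @param gsc a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(gsc$sets, function(s) {
    paste(c(s$term_id, s$term_name, s$members), collapse = "\t")
  }, character(1))
  writeLines(unname(lines), path)
  invisible(NULL)
}
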