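## SAM-style moderated statistics with permutation FDR, used for the
## expressed-set rule, RIP target calling and mutant up/down calls.

#' SAM analysis parameters
#'
#' @param variant `"one_class"`, `"two_class_paired"` or
#'   `"two_class_unpaired"`.
#' @param s0 fudge-factor strategy: `"tusher"` (grid search minimising the
#'   coefficient of variation of d across s-quantile bins, the default),
#'   `"zero"`, or a numeric percentile in `[0,100]` of the per-gene s
#'   values.
#' @param n_permutations maximum number of permutations; enumeration is
#'   exhaustive whenever fewer distinct permutations exist.
#' @param seed RNG seed used when permutations are sampled.
#' @param mu0 one-class reference value; default (`NULL`) is the grand mean
#'   over all genes and samples of the analysed matrix.
#' @param fold_method `"arithmetic"` (default) or `"geometric"` mean of the
#'   per-replicate linear ratios.
#' @return A list of class `sam_params`.
#' @export
sam_params <- function(variant = c("two_class_paired", "two_class_unpaired", "one_class"),
                       s0 = "tusher", n_permutations = 1000L, seed = 1L,
                       mu0 = NULL, fold_method = c("arithmetic", "geometric")) {
  variant <- match.arg(variant)
  if (is.numeric(s0)) {
    if (s0 < 0 || s0 > 100) stop_fmt("s0 percentile must lie in [0,100]")
  } else if (!s0 %in% c("tusher", "zero")) {
    stop_fmt("s0 must be 'tusher', 'zero', or a percentile in [0,100]")
  }
  if (n_permutations < 1L) stop_fmt("n_permutations must be >= 1")
  structure(list(variant = variant, s0 = s0,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), mu0 = mu0,
                 fold_method = match.arg(fold_method)),
            class = "sam_params")
}

#' Two-group / paired design descriptor for SAM
#'
#' @param group factor or character with exactly two levels; the d statistic
#'   measures level 2 minus level 1 (in `levels()` order). `NULL` for the
#'   one-class variant.
#' @param pair pairing key (replicate index) for the paired variant;
#'   each pair must contain one sample of each group.
#' @return list of class `sam_design`.
#' @export
sam_design <- function(group = NULL, pair = NULL) {
  if (!is.null(group)) {
    group <- as.factor(group)
    if (nlevels(group) != 2L) stop_fmt("design group must have exactly 2 levels")
  }
  structure(list(group = group, pair = pair), class = "sam_design")
}

## Per-gene numerator r and spread s for a (possibly permuted) data matrix.
.sam_parts <- function(x, design, variant, mu0 = NULL) {
  if (variant == "two_class_unpaired") {
    g <- design$group
    i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
    n1 <- length(i1); n2 <- length(i2)
    if (n1 < 2L || n2 < 2L) stop_fmt("each group needs >= 2 samples")
    m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
    ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
    ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
    r <- m2 - m1
    s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  } else if (variant == "two_class_paired") {
    z <- .paired_diffs(x, design)
    n <- ncol(z)
    if (n < 2L) stop_fmt("paired variant needs >= 2 pairs")
    zb <- rowMeans(z)
    r <- zb
    s <- sqrt(rowSums((z - zb)^2) / (n * (n - 1)))
  } else { # one_class
    n <- ncol(x)
    if (n < 2L) stop_fmt("one-class variant needs >= 2 samples")
    if (is.null(mu0)) mu0 <- mean(x)
    xb <- rowMeans(x)
    r <- xb - mu0
    s <- sqrt(rowSums((x - xb)^2) / (n * (n - 1)))
  }
  list(r = r, s = s)
}

## Matrix of paired differences (group level 2 minus level 1), one column
## per pair, ordered by pair key.
.paired_diffs <- function(x, design) {
  g <- design$group; pr <- design$pair
  if (is.null(g) || is.null(pr)) stop_fmt("paired variant needs group and pair")
  keys <- sort(unique(pr))
  cols2 <- integer(length(keys)); cols1 <- integer(length(keys))
  for (j in seq_along(keys)) {
    idx <- which(pr == keys[j])
    if (length(idx) != 2L || length(unique(g[idx])) != 2L) {
      stop_fmt("pair '%s' must contain one sample of each group", keys[j])
    }
    cols1[j] <- idx[g[idx] == levels(g)[1]]
    cols2[j] <- idx[g[idx] == levels(g)[2]]
  }
  x[, cols2, drop = FALSE] - x[, cols1, drop = FALSE]
}

## Tusher-style grid search for the fudge factor s0: among candidate
## percentiles of s, pick the one minimising the coefficient of variation
## of the spread of d across s-quantile bins.
.s0_tusher <- function(r, s) {
  cand <- quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE)
  nbin <- max(2L, min(20L, floor(length(s) / 10)))
  bins <- cut(rank(s, ties.method = "first"), breaks = nbin, labels = FALSE)
  cv <- vapply(cand, function(a) {
    d <- r / (s + a)
    v <- tapply(d, bins, function(z) stats::mad(z))
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 2L) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

.resolve_s0 <- function(params, r, s) {
  if (is.numeric(params$s0)) return(quantile(s, params$s0 / 100, names = FALSE))
  if (params$s0 == "zero") {
    if (any(s == 0)) {
      stop_fmt("zero-variance gene(s) with s0 = 0; use a nonzero s0 strategy")
    }
    return(0)
  }
  .s0_tusher(r, s)
}

#' SAM d statistic
#'
#' Moderated difference statistic `d = r / (s + s0)` on log2 data, where
#' `r` and `s` are the variant-specific numerator and spread:
#' unpaired, `r = mean2 - mean1` with the pooled two-sample spread;
#' paired, `r` the mean of per-pair differences with their standard error;
#' one-class, `r = mean - mu0` with the sample-mean standard error.
#'
#' @param x numeric matrix, genes x samples, log2 scale (an `expr_matrix`
#'   is also accepted).
#' @param design a [sam_design()].
#' @param params a [sam_params()].
#' @return Named numeric vector of per-gene d statistics; the resolved `s0`
#'   is attached as `attr(, "s0")`.
#' @export
sam_statistic <- function(x, design = sam_design(), params = sam_params()) {
  if (inherits(x, "expr_matrix")) x <- x$values
  parts <- .sam_parts(x, design, params$variant, params$mu0)
  s0 <- .resolve_s0(params, parts$r, parts$s)
  d <- parts$r / (parts$s + s0)
  names(d) <- rownames(x)
  attr(d, "s0") <- s0
  d
}

## Enumerate (or sample) permutations for the variant. Returns a list whose
## elements parameterise one permutation each.
.sam_permutations <- function(design, variant, n_samples, params) {
  if (variant == "two_class_unpaired") {
    g <- design$group
    n1 <- sum(g == levels(g)[1])
    all_sets <- combn(n_samples, n1, simplify = FALSE)
    if (length(all_sets) <= params$n_permutations) return(list(type = "label", sets = all_sets))
    set.seed(params$seed)
    pick <- sample.int(length(all_sets), params$n_permutations)
    list(type = "label", sets = all_sets[pick])
  } else {
    n <- if (variant == "two_class_paired") {
      length(unique(design$pair))
    } else {
      n_samples
    }
    total <- 2^n
    if (total <= params$n_permutations) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    } else {
      set.seed(params$seed)
      signs <- matrix(sample(c(1, -1), params$n_permutations * n, replace = TRUE),
                      ncol = n)
      signs <- unique(signs)
    }
    list(type = "sign", signs = signs)
  }
}

#' Permutation-based FDR for SAM statistics
#'
#' Computes observed d statistics, then re-computes d under permutations of
#' the design (group-label reassignment for the unpaired variant; sign
#' flips of the per-pair differences for the paired variant; sign flips of
#' the deviations from `mu0` for the one-class variant), holding `s0` fixed
#' at its observed-data value. For a cutoff `c`,
#' `FDR(c) = median_perm #\{|d_perm| >= c\} / #\{|d_obs| >= c\}`, capped at
#' 1; each gene is assigned the FDR at its own `|d|` and the per-gene
#' values are then monotonised (running minimum over decreasing `|d|`) so
#' that thresholding is well defined. Enumeration is exhaustive whenever
#' the number of distinct permutations does not exceed
#' `params$n_permutations`; results are deterministic given
#' `params$seed`.
#'
#' @inheritParams sam_statistic
#' @param fold optional per-gene linear fold-change vector to carry into
#'   the result (e.g. from [fold_enrichment()]).
#' @return A `sam_result`: data.frame with columns `gene_id`, `d`, `fold`,
#'   `fdr`, `rank` (rank 1 = largest `|d|`, ties broken by gene id), with
#'   attributes `s0`, `n_permutations` and `variant`.
#' @export
permutation_fdr <- function(x, design = sam_design(), params = sam_params(),
                            fold = NULL) {
  if (inherits(x, "expr_matrix")) x <- x$values
  variant <- params$variant
  parts <- .sam_parts(x, design, variant, params$mu0)
  s0 <- .resolve_s0(params, parts$r, parts$s)
  d_obs <- parts$r / (parts$s + s0)

  perms <- .sam_permutations(design, variant, ncol(x), params)
  n_perm <- if (perms$type == "label") length(perms$sets) else nrow(perms$signs)
  if (n_perm < 2L) stop_fmt("fewer than 2 distinct permutations available")

  abs_obs <- abs(d_obs)
  ord <- order(-abs_obs, rownames(x))
  cutoffs <- abs_obs[ord]                    # decreasing
  n_ge_obs <- seq_along(cutoffs)             # #{|d_obs| >= cutoff_r}

  mu0 <- params$mu0
  if (variant == "one_class" && is.null(mu0)) mu0 <- mean(x)
  if (variant == "two_class_paired") z_obs <- .paired_diffs(x, design)
  if (variant == "one_class") dev_obs <- x - mu0

  counts <- matrix(0L, nrow = length(cutoffs), ncol = n_perm)
  for (p in seq_len(n_perm)) {
    if (perms$type == "label") {
      g <- design$group
      gp <- factor(rep(levels(g)[2], ncol(x)), levels = levels(g))
      gp[perms$sets[[p]]] <- levels(g)[1]
      pp <- .sam_parts(x, sam_design(group = gp), "two_class_unpaired")
    } else if (variant == "two_class_paired") {
      z <- sweep(z_obs, 2, perms$signs[p, ], `*`)
      n <- ncol(z); zb <- rowMeans(z)
      pp <- list(r = zb, s = sqrt(rowSums((z - zb)^2) / (n * (n - 1))))
    } else {
      dev <- sweep(dev_obs, 2, perms$signs[p, ], `*`)
      n <- ncol(dev); db <- rowMeans(dev)
      pp <- list(r = db, s = sqrt(rowSums((dev - db)^2) / (n * (n - 1))))
    }
    d_perm <- sort(abs(pp$r / (pp$s + s0)))
    # #{|d_perm| >= cutoff} for each decreasing cutoff
    counts[, p] <- length(d_perm) - findInterval(cutoffs, d_perm,
                                                 left.open = TRUE)
  }
  med_false <- apply(counts, 1, median)
  raw_fdr <- pmin(1, med_false / n_ge_obs)
  fdr_sorted <- rev(cummin(rev(raw_fdr)))    # monotone in rank

  fdr <- numeric(length(d_obs))
  fdr[ord] <- fdr_sorted
  rk <- integer(length(d_obs)); rk[ord] <- seq_along(ord)
  if (is.null(fold)) {
    fold <- rep(NA_real_, length(d_obs))
  } else if (!is.null(names(fold))) {
    fold <- fold[rownames(x)]
  }
  res <- data.frame(gene_id = rownames(x), d = unname(d_obs),
                    fold = unname(fold),
                    fdr = fdr, rank = rk, stringsAsFactors = FALSE)
  attr(res, "s0") <- s0
  attr(res, "n_permutations") <- n_perm
  attr(res, "variant") <- variant
  class(res) <- c("sam_result", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-gene linear fold enrichment
#'
#' For a paired design, the mean over replicate pairs of the per-pair
#' linear ratio (group level 2 over level 1); for an unpaired design, the
#' ratio of linear group means. Computed on the linear scale: log2
#' matrices are back-transformed cell-wise first.
#'
#' @inheritParams sam_statistic
#' @param log2 whether `x` is on the log2 scale (taken from the
#'   `expr_matrix` when one is passed).
#' @param method `"arithmetic"` (default) or `"geometric"` mean of the
#'   per-pair ratios.
#' @return Named numeric vector of linear folds (> 0).
#' @export
fold_enrichment <- function(x, design, log2 = TRUE,
                            method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  if (inherits(x, "expr_matrix")) { log2 <- x$log2; x <- x$values }
  lin <- if (log2) 2^x else x
  if (any(lin <= 0)) stop_fmt("zero or negative linear value; fold undefined")
  if (!is.null(design$pair)) {
    num <- .paired_diffs(log(lin), design)   # log ratios per pair
    ratios <- exp(num)
    f <- if (method == "arithmetic") rowMeans(ratios) else exp(rowMeans(log(ratios)))
  } else {
    g <- design$group
    m1 <- rowMeans(lin[, g == levels(g)[1], drop = FALSE])
    m2 <- rowMeans(lin[, g == levels(g)[2], drop = FALSE])
    f <- m2 / m1
  }
  names(f) <- rownames(x)
  f
}

#' Call targets from a SAM result
#'
#' A gene is a target when its linear fold enrichment is at least
#' `min_fold` and its permutation FDR is below `max_fdr` (>= / <
#' semantics, so a gene at exactly the fold threshold is included).
#'
#' @param sam a `sam_result` with a `fold` column.
#' @param min_fold minimum linear fold (default 1.5).
#' @param max_fdr FDR ceiling (default 0.05).
#' @return list with `genes` (character) and `report` (the per-gene
#'   data.frame with logical columns `pass_fold`, `pass_fdr`, `called`).
#' @export
call_targets <- function(sam, min_fold = 1.5, max_fdr = 0.05) {
  report <- as.data.frame(sam)
  report$pass_fold <- !is.na(report$fold) & report$fold >= min_fold
  report$pass_fdr <- report$fdr < max_fdr
  report$called <- report$pass_fold & report$pass_fdr
  list(genes = report$gene_id[report$called], report = report)
}

#' Negatively enriched control set
#'
#' The co-expressed non-targets: expressed genes whose paired d statistic
#' is negative (enriched in the control immunoprecipitate). No fold
#' threshold is applied; an FDR ceiling may optionally be supplied.
#'
#' @param sam a `sam_result`.
#' @param max_fdr optional FDR ceiling (default `NULL`: none).
#' @return Character vector of gene ids.
#' @export
define_negative_set <- function(sam, max_fdr = NULL) {
  keep <- sam$d < 0
  if (!is.null(max_fdr)) keep <- keep & sam$fdr < max_fdr
  sam$gene_id[keep]
}

#' Expressed-set definition by one-class SAM
#'
#' For each condition (unique combination of sample role and timepoint), a
#' one-class SAM against the condition's grand mean identifies genes whose
#' normalised intensity significantly exceeds the array-wide mean (d > 0,
#' FDR < `max_fdr`); the expressed set is the union over conditions.
#'
#' @param em an `expr_matrix` (normalised, log2).
#' @param params a [sam_params()]; the variant is forced to one-class.
#' @param max_fdr FDR ceiling (default 0.05).
#' @return Character vector of expressed gene ids (union over conditions).
#' @export
define_expressed <- function(em, params = sam_params("one_class", s0 = 5),
                             max_fdr = 0.05) {
  params$variant <- "one_class"
  tp <- em$samples$timepoint
  tp[is.na(tp)] <- ""
  cond <- interaction(em$samples$role, tp, drop = TRUE)
  expressed <- character(0)
  for (lv in levels(cond)) {
    sub <- em$values[, cond == lv, drop = FALSE]
    if (ncol(sub) < 2L) next
    p <- params; p$mu0 <- mean(sub)
    res <- permutation_fdr(sub, sam_design(), p)
    expressed <- union(expressed, res$gene_id[res$d > 0 & res$fdr < max_fdr])
  }
  sort(expressed)
}

#' Unchanged-set definition
#'
#' Genes whose linear fold lies strictly inside `(1/max_fold, max_fold)`
#' and whose FDR exceeds `min_fdr` — the co-expressed unchanged controls
#' used for motif enrichment in the mutant time course.
#'
#' @param sam a `sam_result` with a `fold` column.
#' @param max_fold symmetric fold window (default 1.1).
#' @param min_fdr FDR floor (default 0.50).
#' @return Character vector of gene ids.
#' @export
define_unchanged <- function(sam, max_fold = 1.1, min_fdr = 0.50) {
  keep <- !is.na(sam$fold) & sam$fold > 1 / max_fold & sam$fold < max_fold &
    sam$fdr > min_fdr
  sam$gene_id[keep]
}

#' Quantile normalisation
#'
#' Forces every sample column to the same distribution: the mean of the
#' column-sorted values. Ties within a column receive the mean of the tied
#' quantile values; the input row order is preserved. Delegates to
#' `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param x numeric matrix or `expr_matrix` with at least two columns.
#' @return Same type as the input, normalised.
#' @export
quantile_normalize <- function(x) {
  em <- NULL
  if (inherits(x, "expr_matrix")) { em <- x; x <- x$values }
  if (ncol(x) < 2L) stop_fmt("quantile normalisation needs >= 2 samples")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  if (!is.null(em)) { em$values <- out; return(em) }
  out
}
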