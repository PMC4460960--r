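## Cross-cutting statistics: two-sided Fisher tests, multiple-testing
## corrections, quadrant-excluded Spearman, rank-sum comparisons, and the
## generic GMT annotation-enrichment engine.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' `a` counts the in-list/in-set cell. The p-value is the sum of
#' hypergeometric probabilities of all tables with the same margins whose
#' probability does not exceed the observed one (standard two-sided
#' convention, delegated to [stats::fisher.test()]); the direction is read
#' off the odds ratio.
#'
#' @param a,b,c,d non-negative integer counts (`a + b` = list size,
#'   `a + c` = set size).
#' @return list: `p_value`, `odds_ratio` (conditional MLE), `direction`
#'   (`"enriched"` / `"depleted"` / `"none"`), `table`.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop_fmt("negative count in contingency table")
  if (sum(counts) == 0) stop_fmt("empty contingency table")
  tab <- matrix(as.integer(counts), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  orr <- unname(ft$estimate)
  list(p_value = ft$p.value, odds_ratio = orr,
       direction = if (orr > 1) "enriched" else if (orr < 1) "depleted" else "none",
       table = tab)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p numeric p-values in `[0,1]`.
#' @return q-values in the input order (via [stats::p.adjust()], method
#'   `"BH"`).
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_fmt("p-values outside [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni-adjusted p-values
#'
#' @param p numeric p-values.
#' @param m correction count (default `length(p)`; must be at least
#'   `length(p)` when supplied).
#' @return `pmin(1, m * p)` in input order.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (length(p) == 0L) return(numeric(0))
  if (m < length(p)) stop_fmt("m must be >= length(p)")
  pmin(1, m * p)
}

#' Quadrant-excluded Spearman correlation
#'
#' Rank correlation between two linear fold-enrichment vectors on a shared
#' gene universe, after removing genes depleted (fold < 1) in both
#' experiments — the bottom-left quadrant of the log-log enrichment plot,
#' where control-enriched transcripts would otherwise dominate the
#' correlation. Genes sub-threshold in only one experiment are retained.
#' Midranks are used; the p-value comes from [stats::cor.test()] (exact
#' for small tie-free samples, t-approximation otherwise).
#'
#' @param x,y named (or parallel) numeric vectors of linear folds.
#' @return list: `rho`, `p_value`, `n_used`, `n_excluded`.
#' @export
spearman_quadrant_excluded <- function(x, y) {
  if (length(x) != length(y)) stop_fmt("x and y must have equal length")
  if (!is.null(names(x)) && !is.null(names(y))) y <- y[names(x)]
  drop <- x < 1 & y < 1
  xk <- x[!drop]; yk <- y[!drop]
  if (length(xk) < 2L) stop_fmt("fewer than 2 genes remain after quadrant exclusion")
  if (length(xk) == 2L) {
    # rho is defined but no test is possible
    return(list(rho = unname(cor(xk, yk, method = "spearman")), p_value = NA_real_,
                n_used = 2L, n_excluded = sum(drop)))
  }
  ct <- suppressWarnings(stats::cor.test(xk, yk, method = "spearman",
                                         exact = length(xk) <= 10))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_used = length(xk), n_excluded = sum(drop))
}

#' Two-sided rank-sum comparison of two score sets
#'
#' Tie-corrected two-sided Wilcoxon rank-sum test (exact for small
#' tie-free samples via [stats::wilcox.test()]), reporting both medians —
#' used for translation-index and RPKM-ratio comparisons of a target set
#' against all expressed genes.
#'
#' @param a,b numeric score vectors (non-empty).
#' @return list: `p_value`, `median_a`, `median_b`, `n_a`, `n_b`.
#' @export
ranksum_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop_fmt("both score sets must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(p_value = wt$p.value, median_a = median(a), median_b = median(b),
       n_a = length(a), n_b = length(b))
}

#' Annotation-term enrichment over a gene-set collection
#'
#' For every term with more than `min_set_size - 1` background members, a
#' two-sided Fisher test of list membership against set membership within
#' the background universe, corrected within this invocation's term family
#' (`"bh"` or `"bonferroni"`). Terms below the background-size floor are
#' excluded before testing (mirroring the >25-gene rule used for
#' localization-pattern analyses); pass `min_set_size = 1` to disable.
#'
#' @param gene_list character vector, subset of `background`.
#' @param gene_sets a `gene_set_collection` (or named list of member
#'   vectors).
#' @param background character gene universe.
#' @param min_set_size smallest background set size tested (default 26,
#'   i.e. strictly more than 25 members).
#' @param correction `"bh"` or `"bonferroni"`.
#' @return data.frame of class `enrichment_result`: `term_id`,
#'   `term_name`, `n_overlap`, `n_list`, `n_set`, `n_background`,
#'   `direction`, `odds_ratio`, `p_value`, `q_value`, ordered by p.
#' @export
enrich_terms <- function(gene_list, gene_sets, background,
                         min_set_size = 26L, correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  if (length(background) == 0L) stop_fmt("empty background")
  extra <- setdiff(gene_list, background)
  if (length(extra) > 0L) {
    stop_fmt("gene list contains %d gene(s) outside the background (e.g. %s)",
             length(extra), extra[1])
  }
  if (inherits(gene_sets, "gene_set_collection")) {
    sets <- lapply(gene_sets$sets, function(s) s$members)
    names(sets) <- vapply(gene_sets$sets, function(s) s$term_id, character(1))
    term_names <- vapply(gene_sets$sets, function(s) s$term_name, character(1))
  } else {
    sets <- gene_sets
    term_names <- names(sets)
  }
  rows <- list()
  for (i in seq_along(sets)) {
    members <- intersect(sets[[i]], background)
    if (length(members) < min_set_size) next
    a <- length(intersect(gene_list, members))
    b <- length(gene_list) - a
    c0 <- length(members) - a
    d <- length(background) - length(gene_list) - c0
    ft <- fisher_two_sided(a, b, c0, d)
    rows[[length(rows) + 1L]] <-
      data.frame(term_id = names(sets)[i], term_name = term_names[i],
                 n_overlap = a, n_list = length(gene_list),
                 n_set = length(members), n_background = length(background),
                 direction = ft$direction, odds_ratio = ft$odds_ratio,
                 p_value = ft$p_value, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      n_overlap = integer(0), n_list = integer(0),
                      n_set = integer(0), n_background = integer(0),
                      direction = character(0), odds_ratio = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_value <- if (correction == "bh") bh_fdr(out$p_value) else bonferroni(out$p_value)
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Late/early RNA abundance ratio
#'
#' Per-gene ratio of RPKM in 2-4 h embryos over 0-2 h embryos. `0/0` is
#' flagged undefined and `x/0` infinite; both are excluded from rank
#' tests downstream (counts reported in attributes).
#'
#' @param rpkm_table data.frame with columns `gene_id`, `rpkm_0to2`,
#'   `rpkm_2to4` (RPKM >= 0).
#' @return Named numeric vector of ratios (`NA` where undefined, `Inf`
#'   where only the denominator is 0), with attributes `n_undefined` and
#'   `n_infinite`.
#' @export
ratio_2to4_over_0to2 <- function(rpkm_table) {
  need <- c("gene_id", "rpkm_0to2", "rpkm_2to4")
  miss <- setdiff(need, names(rpkm_table))
  if (length(miss) > 0L) stop_fmt("missing column(s): %s", paste(miss, collapse = ", "))
  num <- rpkm_table$rpkm_2to4; den <- rpkm_table$rpkm_0to2
  if (any(num < 0 | den < 0)) stop_fmt("negative RPKM value")
  r <- num / den
  r[num == 0 & den == 0] <- NA_real_
  names(r) <- rpkm_table$gene_id
  attr(r, "n_undefined") <- sum(num == 0 & den == 0)
  attr(r, "n_infinite") <- sum(is.infinite(r))
  r
}

#' Overlap of two gene lists with Fisher significance
#'
#' Venn counts of two lists within a background universe plus the
#' two-sided Fisher test of their association.
#'
#' @param list_a,list_b character gene id vectors (subsets of
#'   `background`).
#' @param background character gene universe.
#' @return list: `n_a`, `n_b`, `n_overlap`, `n_background`, `expected`,
#'   `p_value`, `odds_ratio`, `direction`.
#' @export
compare_lists <- function(list_a, list_b, background) {
  list_a <- intersect(list_a, background)
  list_b <- intersect(list_b, background)
  a <- length(intersect(list_a, list_b))
  b <- length(list_a) - a
  c0 <- length(list_b) - a
  d <- length(background) - a - b - c0
  ft <- fisher_two_sided(a, b, c0, d)
  list(n_a = length(list_a), n_b = length(list_b), n_overlap = a,
       n_background = length(background),
       expected = length(list_a) * length(list_b) / length(background),
       p_value = ft$p_value, odds_ratio = ft$odds_ratio,
       direction = ft$direction)
}
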