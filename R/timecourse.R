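## Consensus k-means under Pearson-correlation distance for decay-class
## assignment from wild-type four-timepoint profiles, with figure-of-merit
## diagnostics and archetype labelling.

#' Per-gene wild-type expression profiles
#'
#' Averages log2 intensities over replicates per timepoint for samples of
#' the requested role, ordered by timepoint label. Genes with a constant
#' profile are routed to an `unclusterable` bucket, since Pearson distance
#' is undefined for them.
#'
#' @param em an `expr_matrix` with `timepoint` metadata.
#' @param role sample role to average (default `"wildtype"`).
#' @param genes optional subset of gene ids.
#' @return list of class `profile_set`: `profiles` (genes x timepoints
#'   matrix), `unclusterable` (character).
#' @export
profile_set <- function(em, role = "wildtype", genes = NULL) {
  keep <- em$samples$role == role
  if (!any(keep)) stop_fmt("no samples with role '%s'", role)
  tps <- sort(unique(em$samples$timepoint[keep]))
  if (length(tps) < 3L) stop_fmt("need >= 3 timepoints (got %d)", length(tps))
  vals <- em$values
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(vals))
    if (length(miss) > 0L) stop_fmt("gene(s) absent from matrix: %s",
                                    paste(head(miss, 3), collapse = ", "))
    vals <- vals[genes, , drop = FALSE]
  }
  prof <- vapply(tps, function(tp) {
    rowMeans(vals[, keep & em$samples$timepoint == tp, drop = FALSE])
  }, numeric(nrow(vals)))
  colnames(prof) <- tps
  const <- apply(prof, 1, function(x) sd(x) < 1e-12)
  structure(list(profiles = prof[!const, , drop = FALSE],
                 unclusterable = rownames(prof)[const]),
            class = "profile_set")
}

## row-standardize (z-score per gene); constant rows become 0
.standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sdev <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(sdev < 1e-12, 1, sdev)
  z[sdev < 1e-12, ] <- 0
  z
}

## Pearson distance matrix between standardized rows and standardized
## centroids: 1 - z %*% t(zc) / (m - 1)
.pearson_dist <- function(z, zc) {
  1 - tcrossprod(z, zc) / (ncol(z) - 1)
}

## one Lloyd run with k-means++-style seeding from the current RNG state
.kmeans_pearson_once <- function(z, k, max_iter = 100L) {
  n <- nrow(z)
  cent_idx <- sample.int(n, 1L)
  zc <- z[cent_idx, , drop = FALSE]
  for (j in seq_len(k - 1L)) {
    d2 <- apply(.pearson_dist(z, zc), 1, min)^2
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    zc <- rbind(zc, z[pick, , drop = FALSE])
  }
  labels <- integer(n)
  for (iter in seq_len(max_iter)) {
    D <- .pearson_dist(z, zc)
    new_labels <- max.col(-D, ties.method = "first")
    # empty clusters: re-seed at the point farthest from its centroid
    for (cl in seq_len(k)) {
      if (!any(new_labels == cl)) {
        far <- which.max(D[cbind(seq_len(n), new_labels)])
        new_labels[far] <- cl
      }
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    zc <- .standardize_rows(t(vapply(seq_len(k), function(cl) {
      colMeans(z[labels == cl, , drop = FALSE])
    }, numeric(ncol(z)))))
  }
  D <- .pearson_dist(z, zc)
  list(labels = labels, centroids = zc,
       total_distance = sum(D[cbind(seq_len(nrow(z)), labels)]),
       iterations = iter)
}

#' k-means clustering under Pearson-correlation distance
#'
#' Lloyd iterations on per-gene standardized profiles with distance
#' `1 - r`; centroids are re-standardized means of their members.
#' Seeding is k-means++-style from the seeded generator; an emptied
#' cluster is re-seeded at the point farthest from its assigned centroid.
#' Deterministic given the seed.
#'
#' @param profiles a `profile_set` or a genes x timepoints matrix with
#'   no constant rows.
#' @param k number of clusters (default 6).
#' @param seed RNG seed.
#' @param max_iter Lloyd iteration cap.
#' @return list: `labels` (named integer in 1..k), `centroids`
#'   (k x timepoints, standardized), `total_distance`.
#' @export
kmeans_pearson <- function(profiles, k = 6L, seed = 1L, max_iter = 100L) {
  x <- if (inherits(profiles, "profile_set")) profiles$profiles else profiles
  if (nrow(x) < k) stop_fmt("need at least k = %d non-constant profiles", k)
  z <- .standardize_rows(x)
  set.seed(seed)
  fit <- .kmeans_pearson_once(z, k, max_iter)
  names(fit$labels) <- rownames(x)
  rownames(fit$centroids) <- paste0("cluster", seq_len(k))
  colnames(fit$centroids) <- colnames(x)
  fit
}

## canonical partition key: relabel clusters by first occurrence
.partition_key <- function(labels) {
  canon <- match(labels, unique(labels))
  paste(canon, collapse = ",")
}

#' Consensus clustering over repeated k-means restarts
#'
#' Runs `n_restarts` seeded k-means restarts; two runs are "the same"
#' iff their partitions are identical after one-to-one cluster matching
#' (equivalently, equal as set partitions). Reports the modal partition
#' and the fraction of restarts producing it, with a warning when the
#' modal frequency falls below `min_frequency`.
#'
#' @inheritParams kmeans_pearson
#' @param n_restarts number of restarts (default 100).
#' @param min_frequency consensus warning threshold (default 0.5).
#' @return list of class `cluster_result`: `labels` (named, canonical
#'   1..k), `centroids`, `archetype` (per-cluster tag from
#'   [label_archetypes()]), `modal_frequency`, `n_restarts`,
#'   `partition_table` (counts of distinct partitions).
#' @export
consensus_clusters <- function(profiles, k = 6L, n_restarts = 100L, seed = 1L,
                               max_iter = 100L, min_frequency = 0.5) {
  x <- if (inherits(profiles, "profile_set")) profiles$profiles else profiles
  if (nrow(x) < k) stop_fmt("need at least k = %d non-constant profiles", k)
  z <- .standardize_rows(x)
  keys <- character(n_restarts)
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    fit <- .kmeans_pearson_once(z, k, max_iter)
    keys[r] <- .partition_key(fit$labels)
    fits[[r]] <- fit
  }
  tab <- sort(table(keys), decreasing = TRUE)
  modal_key <- names(tab)[1]
  freq <- as.numeric(tab[1]) / n_restarts
  if (freq < min_frequency) {
    warning(sprintf("modal partition frequency %.2f below %.2f: clustering is unstable",
                    freq, min_frequency))
  }
  fit <- fits[[match(modal_key, keys)]]
  canon <- match(fit$labels, unique(fit$labels))
  # centroids in canonical label order
  zc <- .standardize_rows(t(vapply(seq_len(k), function(cl) {
    colMeans(z[canon == cl, , drop = FALSE])
  }, numeric(ncol(z)))))
  rownames(zc) <- paste0("cluster", seq_len(k))
  colnames(zc) <- colnames(x)
  labels <- stats::setNames(canon, rownames(x))
  structure(list(labels = labels, centroids = zc,
                 archetype = label_archetypes(zc),
                 modal_frequency = freq, n_restarts = n_restarts,
                 partition_table = tab),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d genes, k=%d, modal frequency %.2f>\n",
              length(x$labels), nrow(x$centroids), x$modal_frequency))
  print(table(archetype = x$archetype[x$labels]))
  invisible(x)
}

#' Figure of merit for choosing k
#'
#' Leave-one-timepoint-out diagnostic: for each held-out timepoint the
#' remaining timepoints are clustered (best of `n_restarts` seeded runs)
#' and the root mean within-cluster variance of the held-out timepoint is
#' computed, scaled by the standard adjustment factor
#' `sqrt(n / (n - k))`; the curve of the mean FOM over held-out choices is
#' returned for visual inspection — no elbow is picked automatically.
#' Profiles are standardized over all timepoints before the procedure.
#'
#' @inheritParams kmeans_pearson
#' @param k_range integer vector of cluster counts to evaluate.
#' @param n_restarts restarts per leave-one-out clustering (default 5).
#' @return data.frame with columns `k` and `fom`.
#' @export
figure_of_merit <- function(profiles, k_range = 2:8, seed = 1L, n_restarts = 5L) {
  x <- if (inherits(profiles, "profile_set")) profiles$profiles else profiles
  m <- ncol(x)
  if (m < 3L) stop_fmt("need >= 3 timepoints")
  if (max(k_range) >= nrow(x)) stop_fmt("k_range maximum must be below the gene count")
  z <- .standardize_rows(x)
  n <- nrow(z)
  fom <- vapply(k_range, function(k) {
    per_tp <- vapply(seq_len(m), function(tp) {
      ztr <- .standardize_rows(z[, -tp, drop = FALSE])
      best <- NULL
      for (r in seq_len(n_restarts)) {
        set.seed(seed + 1000L * tp + r)
        fit <- .kmeans_pearson_once(ztr, k)
        if (is.null(best) || fit$total_distance < best$total_distance) best <- fit
      }
      held <- z[, tp]
      ss <- sum(vapply(seq_len(k), function(cl) {
        v <- held[best$labels == cl]
        sum((v - mean(v))^2)
      }, numeric(1)))
      sqrt(ss / n) * sqrt(n / (n - k))
    }, numeric(1))
    mean(per_tp)
  }, numeric(1))
  data.frame(k = as.integer(k_range), fom = fom)
}

#' Archetype tags for cluster centroids
#'
#' Classifies each standardized centroid over four ordered timepoints:
#' maternal-decay family when the profile starts high and declines
#' ("A-like" decline then re-expression, "B-like" monotone decline,
#' "C-like" flat through the first two timepoints then decline); zygotic
#' family when the second timepoint exceeds the first ("D/E/F-like" by
#' whether the maximum falls at t2/t3/t4). Centroids within tolerance of
#' two rules are tagged "mixed" rather than forced. Tags are descriptive,
#' not identities.
#'
#' @param centroids k x 4 matrix (rows standardized internally).
#' @param tol rule tolerance on the standardized scale (default 0.25).
#' @return Character vector of tags, one per centroid row.
#' @export
label_archetypes <- function(centroids, tol = 0.25) {
  if (ncol(centroids) != 4L) stop_fmt("archetype rules expect 4 timepoints")
  z <- .standardize_rows(centroids)
  apply(z, 1, function(v) {
    if (v[2] - v[1] > tol) {
      peak <- which.max(v)
      if (peak == 1L) return("mixed")
      return(c("D-like", "E-like", "F-like")[peak - 1L])
    }
    declined <- min(v[2], v[3]) < v[1] - tol
    if (!declined) return("mixed")
    if (v[4] - v[3] > tol) return("A-like")
    if (abs(v[1] - v[2]) <= tol && v[3] < v[2] - tol) return("C-like")
    if (v[2] < v[1] - tol) return("B-like")
    "mixed"
  })
}
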