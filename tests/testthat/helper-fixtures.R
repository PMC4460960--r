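# Shared fixture builders; everything is generated in code at test time.

# tiny paired RIP/control matrix (log2) with explicit values
tiny_rip_matrix <- function(values, n_rep = 3L) {
  genes <- rownames(values)
  ids <- c(sprintf("RIP_%d", seq_len(n_rep)), sprintf("CTRL_%d", seq_len(n_rep)))
  colnames(values) <- ids
  samples <- data.frame(sample_id = ids,
                        role = rep(c("RIP", "control"), each = n_rep),
                        replicate = rep(seq_len(n_rep), 2L),
                        stringsAsFactors = FALSE)
  expr_matrix(values, samples, log2 = TRUE)
}

paired_design <- function(em) {
  sam_design(group = factor(em$samples$role, levels = c("control", "RIP")),
             pair = em$samples$replicate)
}

# brute-force AUROC by pair enumeration (oracle)
auroc_bruteforce <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# brute-force two-sided Fisher p by hypergeometric enumeration (oracle)
fisher_bruteforce <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# linear de Bruijn-order string over ACGU containing every k-mer exactly
# once (Martin's prefer-largest greedy construction)
debruijn_rna <- function(k) {
  alpha <- c("A", "C", "G", "U")
  seq_sym <- rep(1L, k - 1L)
  seen <- new.env(parent = emptyenv())
  repeat {
    tail_km <- seq_sym[(length(seq_sym) - k + 2L):length(seq_sym)]
    added <- FALSE
    for (sym in 4:1) {
      key <- paste(c(tail_km, sym), collapse = "")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        seq_sym <- c(seq_sym, sym)
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  paste(alpha[seq_sym], collapse = "")
}
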