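# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package code paths they check.

# Reference greedy clumping: repeatedly scan the full remaining table for
# the smallest p below the threshold, then drop correlated neighbors.
oracle_clump <- function(stats, dosages, r2 = 0.1, window_kb = 250,
                         p_threshold = 1) {
  remaining <- stats
  chosen <- character(0)
  while (nrow(remaining) > 0) {
    elig <- remaining[remaining$p < p_threshold, , drop = FALSE]
    if (nrow(elig) == 0) break
    elig <- elig[order(elig$p, elig$chr, elig$pos), , drop = FALSE]
    idx <- elig[1L, ]
    chosen <- c(chosen, idx$variant_id)
    remaining <- remaining[remaining$variant_id != idx$variant_id, , drop = FALSE]
    if (nrow(remaining) > 0) {
      drop <- logical(nrow(remaining))
      for (j in seq_len(nrow(remaining))) {
        r <- remaining[j, ]
        if (r$chr == idx$chr && abs(r$pos - idx$pos) <= window_kb * 1000) {
          cc <- suppressWarnings(stats::cor(dosages[, idx$variant_id],
                                            dosages[, r$variant_id]))
          if (!is.na(cc) && cc^2 > r2) drop[j] <- TRUE
        }
      }
      remaining <- remaining[!drop, , drop = FALSE]
    }
  }
  sort(chosen)
}

# Exact maximum independent set size by branch-and-bound (n <= ~20).
oracle_mis_size <- function(adj) {
  n <- nrow(adj)
  best <- 0L
  recurse <- function(cand, size) {
    if (length(cand) == 0) {
      best <<- max(best, size)
      return(invisible())
    }
    if (size + length(cand) <= best) return(invisible())
    v <- cand[1L]
    nb <- which(adj[v, ])
    recurse(setdiff(cand[-1L], nb), size + 1L)
    recurse(cand[-1L], size)
  }
  recurse(seq_len(n), 0L)
  best
}

# Hand-coded Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Monte-Carlo oracle for the dosage correlation implied by the Gaussian
# copula threshold model: two latent normals with correlation rho,
# thresholded at the two allele frequencies. Haplotypes are independent, so
# the dosage correlation equals the single-haplotype allele correlation.
oracle_copula_dosage_cor <- function(rho, maf1, maf2, n = 1e6) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  stats::cor(z1 < stats::qnorm(maf1), z2 < stats::qnorm(maf2))
}

# Small logged expression container around a samples x transcripts matrix.
make_logged_expr <- function(Y_t, sample_ids, cell_type = "PBMC") {
  expr_matrix(Y_t, sample_ids = sample_ids, cell_type = cell_type,
              stage = "logged")
}
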