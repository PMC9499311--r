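# Shared fixtures and independent oracles used across the suite.

# Noiseless repair values from the KJMA form, bypassing repair_fraction
# where a test needs independence from the implementation.
kjma_forward <- function(m, tau, theta, times) {
  theta * (1 - exp(-(times / tau)^m))
}

# Brute-force distance correlation: explicit-loop double centering,
# independent of the vectorized implementation.
dc_oracle <- function(u, v) {
  n <- length(u)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a[i, j] <- abs(u[i] - u[j])
    b[i, j] <- abs(v[i] - v[j])
  }
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- mean(A * B)
  dvar_u <- mean(A * A)
  dvar_v <- mean(B * B)
  sqrt(dcov2 / sqrt(dvar_u * dvar_v))
}

# A tiny GRanges signal track from parallel vectors.
make_track <- function(chrom, pos1, score, strand = "*") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos1, width = 1L),
                               strand = strand)
  S4Vectors::mcols(gr)$score <- score
  gr
}
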