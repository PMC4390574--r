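# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately avoid the package's own code paths.

# step-up BH by the textbook definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m))
    adj_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# two-sided Fisher exact p by exhaustive enumeration over tables with the
# observed margins
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive omega maximization for small matrices
omega_oracle <- function(r2, positions, min_window = 2L) {
  S <- nrow(r2)
  focal <- (positions[-S] + positions[-1]) / 2
  best <- -Inf
  for (f in focal) {
    ell <- sum(positions < f)
    if (ell < min_window || S - ell < min_window) next
    for (nl in min_window:ell) for (nr in min_window:(S - ell)) {
      idx <- (ell - nl + 1):(ell + nr)
      sub <- r2[idx, idx, drop = FALSE]
      l <- nl; ss <- nl + nr
      wl <- sum(sub[1:l, 1:l][upper.tri(diag(l))])
      wr <- sum(sub[(l + 1):ss, (l + 1):ss][upper.tri(diag(ss - l))])
      bt <- sum(sub[1:l, (l + 1):ss])
      v <- ((wl + wr) / (choose(l, 2) + choose(ss - l, 2))) /
        (bt / (l * (ss - l)) + 1e-12)
      if (v > best) best <- v
    }
  }
  best
}

# sweep-distorted spectrum by direct enumeration of the generative story
sweep_spectrum_oracle <- function(probs, n, pe) {
  bf <- numeric(n + 1)
  for (k in 0:n) {
    wk <- stats::dbinom(k, n, pe)
    if (k == n) { bf[2:n] <- bf[2:n] + wk * probs; next }
    m <- k + 1
    for (j in 0:m) {
      pj <- sum(probs * stats::dhyper(j, 1:(n - 1), n - 1:(n - 1), m))
      if (j >= 1)
        bf[(j - 1 + n - k) + 1] <- bf[(j - 1 + n - k) + 1] + wk * pj * j / m
      bf[j + 1] <- bf[j + 1] + wk * pj * (1 - j / m)
    }
  }
  bf[2:n] / sum(bf[2:n])
}

# alignment from per-sequence codon strings (vectors of 3-letter codons)
aln_from_codons <- function(..., species, frame_offset = 0L) {
  seqs <- vapply(list(...), paste, character(1), collapse = "")
  names(seqs) <- paste0("s", seq_along(seqs))
  locus_alignment(seqs, species, frame_offset = frame_offset)
}

# write a temporary FASTA file, returning its path
write_tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(nm)
    c(paste0(">", nm), seqs[[nm]]))), path)
  path
}
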