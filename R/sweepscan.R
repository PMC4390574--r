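## SweepFinder/SweeD-style composite likelihood ratio scan. The sweep model
## distorts a background SFS phi: at distance d from the sweep, each lineage
## escapes with probability P_e(d) = 1 - exp(-alpha_s * d); non-escapers
## collapse onto one pre-sweep lineage.

#' Background SFS probabilities
#' @param probs Non-negative weights over derived counts `1..n-1`
#'   (normalized internally).
#' @param n Sample size.
#' @return A `background_sfs`.
#' @export
background_sfs <- function(probs, n) {
  if (length(probs) != n - 1L || any(probs < 0) || sum(probs) <= 0)
    stop_sweepmk("sweepmk_config_error", "invalid background SFS")
  structure(list(probs = probs / sum(probs), n = as.integer(n)),
            class = "background_sfs")
}

## Empirical background with pseudocount 0.5 per bin (SweeD-like behaviour
## on short single loci: the locus is its own background).
empirical_background <- function(dac, n, pseudocount = 0.5) {
  background_sfs(tabulate(dac, nbins = n - 1L) + pseudocount, n)
}

## P(observable derived count b | k lineages escape), b = 0..n, k = 0..n.
## The k+1 pre-sweep lineages (k escapers + 1 collapsed carrying the n-k
## non-escapers) receive derived counts by hypergeometric projection of phi
## to size k+1; the collapsed lineage is derived with probability j/(k+1).
sweep_mix_matrix <- function(phi) {
  n <- phi$n
  M <- matrix(0, n + 1L, n + 1L)  # rows b+1, cols k+1
  for (k in 0:(n - 1L)) {
    m <- k + 1L
    proj <- vapply(0:m, function(j)
      sum(phi$probs * stats::dhyper(j, seq_len(n - 1L),
                                    n - seq_len(n - 1L), m)),
      numeric(1))
    for (j in 0:m) {
      pj <- proj[j + 1L]
      if (pj == 0) next
      w <- j / m
      if (j >= 1L) {
        b_coll <- (j - 1L) + (n - k)      # collapsed lineage derived
        M[b_coll + 1L, k + 1L] <- M[b_coll + 1L, k + 1L] + pj * w
      }
      M[j + 1L, k + 1L] <- M[j + 1L, k + 1L] + pj * (1 - w)
    }
  }
  M[2:n, n + 1L] <- phi$probs  # all lineages escape: background unchanged
  M
}

#' Sweep-distorted site frequency spectrum
#'
#' Distribution of the derived-allele count at a site a physical distance
#' `d` from a sweep of intensity `alpha_s`, renormalized on segregating
#' outcomes `1..n-1`.
#'
#' @param phi A `background_sfs`.
#' @param alpha_s Sweep intensity (per bp), `>= 0`; `Inf` returns `phi`.
#' @param d Distance from the sweep position (bp), `>= 0`.
#' @return Probability vector over derived counts `1..n-1`.
#' @export
sweep_spectrum <- function(phi, alpha_s, d) {
  if (alpha_s < 0 || d < 0)
    stop_sweepmk("sweepmk_config_error", "alpha_s and d must be >= 0")
  pe <- if (is.infinite(alpha_s) || is.infinite(d)) 1 else -expm1(-alpha_s * d)
  sweep_spectrum_pe(sweep_mix_matrix(phi), phi$n, pe)
}

sweep_spectrum_pe <- function(M, n, pe) {
  wk <- stats::dbinom(0:n, n, pe)
  mix <- as.vector(M %*% wk)
  seg <- mix[2:n]
  Z <- sum(seg)
  if (Z < 1e-300)
    stop_sweepmk("sweepmk_renormalization_error",
                 "no segregating outcomes under the sweep model (P_e ~ 0)")
  seg / Z
}

#' Composite likelihood ratio sweep scan
#'
#' For each candidate sweep position `x`,
#' `CLR(x) = 2 * (max_a sum_i log p*(b_i; a, |pos_i - x|) - sum_i log phi(b_i))`,
#' maximized over the intensity grid. The null is nested (infinite
#' intensity recovers the background), so `CLR >= 0` everywhere. Ties in
#' the argmax resolve to the smallest position, then smallest intensity.
#'
#' @param data A `haplotype_matrix`, or a data frame with columns
#'   `position` (bp), `derived_count`, and sample size `n` as an attribute
#'   or column.
#' @param phi Background SFS; default is the data's own empirical spectrum
#'   with pseudocount 0.5 per bin.
#' @param position_grid Candidate sweep positions (bp); default one point
#'   per `grid_bp`, ends included.
#' @param alpha_grid Intensity grid (per bp); default 12 log-spaced values
#'   spanning weak to strong distortion over the locus; `Inf` (the null)
#'   is always appended.
#' @param grid_bp Default spacing of the position grid.
#' @param folded Use folded spectra (no outgroup polarization); the
#'   background is symmetrized before the sweep distortion is applied.
#' @return A `scan_result`: `max_CLR`, `argmax_position`, `argmax_alpha`,
#'   and the per-grid-point `curve` data frame.
#' @export
clr_scan <- function(data, phi = NULL, position_grid = NULL,
                     alpha_grid = NULL, grid_bp = 500, folded = FALSE) {
  if (inherits(data, "haplotype_matrix")) {
    L <- data$locus_length_bp
    pos <- data$positions * L
    dac <- colSums(data$mat)
    n <- data$n
  } else {
    pos <- data$position
    dac <- data$derived_count
    n <- attr(data, "n", exact = TRUE) %||% data$n[1]
    L <- max(pos, 1)
  }
  if (length(dac) < 1L)
    stop_sweepmk("sweepmk_empty_data_error", "no segregating sites to scan")
  if (any(dac < 1L | dac > n - 1L))
    stop_sweepmk("sweepmk_input_error",
                 "derived counts must lie in 1..n-1")
  if (folded) dac <- pmin(dac, n - dac)
  if (is.null(phi)) {
    phi <- if (folded) {
      cnt <- tabulate(dac, nbins = n %/% 2L) + 0.5
      sym <- numeric(n - 1L)
      for (j in seq_len(n %/% 2L)) {
        if (j == n - j) sym[j] <- cnt[j]
        else { sym[j] <- sym[j] + cnt[j] / 2; sym[n - j] <- sym[n - j] + cnt[j] / 2 }
      }
      background_sfs(sym, n)
    } else empirical_background(dac, n)
  }
  if (is.null(position_grid))
    position_grid <- unique(c(seq(0, L, by = grid_bp), L))
  if (is.null(alpha_grid))
    alpha_grid <- exp(seq(log(0.2 / L), log(200 / L), length.out = 12))
  alpha_grid <- sort(unique(c(alpha_grid, Inf)))
  M <- sweep_mix_matrix(phi)
  fold_probs <- function(p) {
    fp <- numeric(n %/% 2L)
    for (i in seq_len(n - 1L)) fp[min(i, n - i)] <- fp[min(i, n - i)] + p[i]
    fp
  }
  ll_bg <- if (folded) sum(log(fold_probs(phi$probs)[dac]))
           else sum(log(phi$probs[dac]))
  curve <- data.frame(position = position_grid, CLR = NA_real_,
                      alpha_hat = NA_real_)
  kk <- 0:n
  for (gi in seq_along(position_grid)) {
    x <- position_grid[gi]
    d <- abs(pos - x)
    best <- -Inf; best_a <- NA_real_
    for (a in alpha_grid) {
      pe <- if (is.infinite(a)) rep(1, length(d)) else -expm1(-a * d)
      ## mixture over escape counts, all sites at once: (n+1) x S
      WK <- vapply(pe, function(p) stats::dbinom(kk, n, p),
                   numeric(n + 1L))
      mix <- M %*% WK
      Z <- colSums(mix[2:n, , drop = FALSE])
      if (any(Z < 1e-300)) { next }  # P_e ~ 0 at some site: model degenerate
      psite <- if (folded) {
        vapply(seq_along(d), function(s)
          fold_probs(mix[2:n, s] / Z[s])[dac[s]], numeric(1))
      } else {
        mix[cbind(dac + 1L, seq_along(d))] / Z
      }
      ll <- sum(log(psite))
      if (ll > best + 1e-12) { best <- ll; best_a <- a }
    }
    curve$CLR[gi] <- max(0, 2 * (best - ll_bg))
    curve$alpha_hat[gi] <- best_a
  }
  imax <- which.max(curve$CLR)  # which.max takes the first (smallest position)
  structure(list(max_CLR = curve$CLR[imax],
                 argmax_position = curve$position[imax],
                 argmax_alpha = curve$alpha_hat[imax],
                 curve = curve, n = n, folded = folded),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("CLR scan: max_CLR = %.3f at %.0f bp (alpha = %.3g)\n",
              x$max_CLR, x$argmax_position, x$argmax_alpha))
  invisible(x)
}

#' Empirical p-value against a simulated null
#'
#' Add-one rule `p = (1 + #\{null >= observed\}) / (length(null) + 1)`;
#' never returns 0, and ties count against significance.
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null statistic values (a
#'   `null_distribution` is also accepted).
#' @return Empirical p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null) {
  if (inherits(null, "null_distribution")) null <- null$values
  if (!length(null))
    stop_sweepmk("sweepmk_config_error", "empty null distribution")
  (1 + sum(null >= observed)) / (length(null) + 1)
}
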