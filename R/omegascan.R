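## OmegaPlus-style omega statistic: ratio of within-flank to between-flank
## average pairwise r^2, maximized over split points and window extents.

#' Squared allelic correlation between two biallelic sites
#'
#' `r^2 = (p_AB - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B))`, computed over
#' samples non-missing at both sites.
#'
#' @param site_i,site_j 0/1 vectors (NA allowed for missing entries).
#' @return r-squared in `[0, 1]`.
#' @export
r_squared <- function(site_i, site_j) {
  keep <- !is.na(site_i) & !is.na(site_j)
  a <- site_i[keep]; b <- site_j[keep]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop_sweepmk("sweepmk_undefined_ld_error",
                 "monomorphic column after missing-data removal")
  D <- mean(a * b) - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Pairwise r-squared matrix of a haplotype sample
#'
#' @param data A `haplotype_matrix` or 0/1 matrix (samples x sites).
#' @param positions Site positions (taken from the `haplotype_matrix` when
#'   omitted).
#' @param drop_singletons Exclude sites with minor-allele count 1
#'   (default `TRUE`; singleton LD is noise-dominated).
#' @return An `ld_matrix`: symmetric `r2` matrix with unit diagonal and
#'   the retained `positions`.
#' @export
ld_matrix <- function(data, positions = NULL, drop_singletons = TRUE) {
  if (inherits(data, "haplotype_matrix")) {
    mat <- data$mat
    positions <- positions %||% (data$positions * data$locus_length_bp)
  } else mat <- data
  if (is.null(positions)) positions <- seq_len(ncol(mat))
  n <- nrow(mat)
  mac <- pmin(colSums(mat), n - colSums(mat))
  keep <- mac >= if (drop_singletons) 2L else 1L
  mat <- mat[, keep, drop = FALSE]; positions <- positions[keep]
  S <- ncol(mat)
  r2 <- diag(nrow = S)
  if (S >= 2L) {
    ## correlation form: r^2 is the squared Pearson correlation of 0/1 columns
    cm <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
    r2 <- cm^2
    diag(r2) <- 1
  }
  structure(list(r2 = r2, positions = positions, S = S),
            class = "ld_matrix")
}

## Within/between block r^2 sums in O(1) per query via a summed-area table.
ld_sat <- function(r2) apply(apply(r2, 1, cumsum), 1, cumsum)

block_sum <- function(sat, r1, r2c, c1, c2) {
  a <- sat[r2c, c2]
  b <- if (r1 > 1) sat[r1 - 1, c2] else 0
  cc <- if (c1 > 1) sat[r2c, c1 - 1] else 0
  d <- if (r1 > 1 && c1 > 1) sat[r1 - 1, c1 - 1] else 0
  a - b - cc + d
}

#' Omega statistic at a fixed split
#'
#' With sites `1..S` split after site `ell`,
#' `omega = [ (C(l,2)+C(S-l,2))^-1 (sum r2 left + sum r2 right) ] /
#'          [ (l (S-l))^-1 sum r2 between + eps ]`.
#'
#' @param ld An `ld_matrix` (or plain symmetric r2 matrix).
#' @param ell Split index, `2 <= ell <= S-2`.
#' @param eps Denominator regularizer (default `1e-12`); a zero
#'   between-block sum yields a finite, flagged value.
#' @return Omega (numeric, attribute `denominator_zero` when regularized).
#' @export
omega_at_split <- function(ld, ell, eps = 1e-12) {
  r2 <- if (inherits(ld, "ld_matrix")) ld$r2 else ld
  S <- nrow(r2)
  if (S < 4L)
    stop_sweepmk("sweepmk_insufficient_sites_error",
                 "omega needs at least 4 sites, got %d", S)
  if (ell < 2L || ell > S - 2L)
    stop_sweepmk("sweepmk_config_error", "split ell=%d outside 2..S-2", ell)
  sat <- ld_sat(r2)
  omega_from_sat(sat, 1L, ell, S, eps = eps)
}

omega_from_sat <- function(sat, lo, ell, hi, eps = 1e-12) {
  nl <- ell - lo + 1L; nr <- hi - ell
  wl <- (block_sum(sat, lo, ell, lo, ell) - nl) / 2      # upper triangle
  wr <- (block_sum(sat, ell + 1L, hi, ell + 1L, hi) - nr) / 2
  bt <- block_sum(sat, lo, ell, ell + 1L, hi)
  num <- (wl + wr) / (choose(nl, 2) + choose(nr, 2))
  den <- bt / (nl * nr) + eps
  out <- num / den
  attr(out, "denominator_zero") <- bt == 0
  out
}

#' Maximized omega over focal points and window extents
#'
#' For each focal point, omega is evaluated on every pair of flanking
#' windows holding between `min_window` and `max_window` sites immediately
#' left and right of the focal point, and the global maximum is reported.
#' Ties resolve to the smallest focal position.
#'
#' @param data A `haplotype_matrix`, `ld_matrix`, or 0/1 matrix.
#' @param focal_grid Focal positions (bp); default the midpoints between
#'   consecutive retained sites.
#' @param min_window,max_window Window bounds in number of sites
#'   (defaults 2 and all sites).
#' @param drop_singletons Passed to [ld_matrix()].
#' @return An `omega_result`: `max_omega`, `argmax_focal`, window bounds,
#'   and the per-focal-point `curve`.
#' @export
omega_max <- function(data, focal_grid = NULL, min_window = 2L,
                      max_window = Inf, drop_singletons = TRUE) {
  ld <- if (inherits(data, "ld_matrix")) data
        else ld_matrix(data, drop_singletons = drop_singletons)
  S <- ld$S
  if (S < 4L || S < 2L * min_window)
    stop_sweepmk("sweepmk_insufficient_sites_error",
                 "omega scan needs >= max(4, 2*min_window) informative sites, got %d", S)
  if (is.null(focal_grid))
    focal_grid <- (ld$positions[-S] + ld$positions[-1]) / 2
  sat <- ld_sat(ld$r2)
  best <- -Inf; arg <- list()
  curve <- data.frame(focal = focal_grid, omega = NA_real_,
                      ell = NA_integer_, lo = NA_integer_, hi = NA_integer_)
  for (fi in seq_along(focal_grid)) {
    f <- focal_grid[fi]
    ell <- sum(ld$positions < f)  # sites strictly left of the focal point
    nl_max <- min(ell, max_window); nr_max <- min(S - ell, max_window)
    if (ell < min_window || S - ell < min_window) next
    ## vectorized over all (nl, nr) window pairs via the summed-area table
    nls <- min_window:nl_max; nrs <- min_window:nr_max
    los <- ell - nls + 1L; his <- ell + nrs
    sat0 <- function(r, cc) ifelse(r < 1L | cc < 1L, 0, sat[cbind(pmax(r, 1L), pmax(cc, 1L))])
    wl <- (sat[ell, ell] - sat0(los - 1L, ell) - sat0(ell, los - 1L) +
             sat0(los - 1L, los - 1L) - nls) / 2
    wr <- (sat[cbind(his, his)] - sat[ell, his] - sat[his, ell] +
             sat[ell, ell] - nrs) / 2
    bt <- outer(los, his, function(lo, hi)
      sat[cbind(rep(ell, length(lo)), hi)] - sat0(lo - 1L, hi) -
        sat[cbind(rep(ell, length(lo)), rep(ell, length(lo)))] +
        sat0(lo - 1L, rep(ell, length(lo))))
    num <- outer(wl, wr, `+`) / outer(choose(nls, 2), choose(nrs, 2), `+`)
    den <- bt / outer(nls, nrs) + 1e-12
    vals <- num / den
    im <- arrayInd(which.max(vals), dim(vals))
    fbest <- vals[im]; fargs <- c(nls[im[1]], nrs[im[2]])
    curve$omega[fi] <- fbest
    curve$ell[fi] <- ell
    curve$lo[fi] <- ell - fargs[1] + 1L
    curve$hi[fi] <- ell + fargs[2]
    if (fbest > best + 1e-12) {
      best <- fbest
      arg <- list(focal = f, ell = ell, lo = ell - fargs[1] + 1L,
                  hi = ell + fargs[2])
    }
  }
  if (!is.finite(best))
    stop_sweepmk("sweepmk_insufficient_sites_error",
                 "no focal point with enough flanking sites")
  structure(list(max_omega = best, argmax_focal = arg$focal,
                 argmax_split = arg$ell, window = c(arg$lo, arg$hi),
                 curve = curve, S = S), class = "omega_result")
}

#' @export
print.omega_result <- function(x, ...) {
  cat(sprintf("omega scan: max_omega = %.3f at focal %.0f (split %d, sites %d..%d of %d)\n",
              x$max_omega, x$argmax_focal, x$argmax_split,
              x$window[1], x$window[2], x$S))
  invisible(x)
}
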