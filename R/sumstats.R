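## Per-locus polymorphism summaries and site-frequency spectra.

harmonic_number <- function(n) sum(1 / seq_len(n))

#' Per-locus polymorphism summary statistics
#'
#' Segregating sites, per-site Watterson's theta and pairwise diversity,
#' with the synonymous/nonsynonymous decomposition of pi over retained
#' coding columns (complete deletion).
#'
#' @param aln A `locus_alignment`.
#' @param species Species tag whose sample is summarized (`"ingroup1"` or
#'   `"ingroup2"`).
#' @param sites `"all"` (default, DnaSP-like): `S`, `theta_w` and
#'   `pi_total` run over every gap/N-free column; `"coding"` restricts
#'   them to complete-codon columns. The synonymous/nonsynonymous
#'   decomposition always uses the classified codon columns.
#' @param classification Optional precomputed `classify_sites` result.
#' @return A `summary_stats` list: `S`, `theta_w`, `pi_total`, `pi_syn`,
#'   `pi_non`, `n`, `L`, `L_syn`, `L_nonsyn`.
#' @export
summarize_locus <- function(aln, species, sites = c("all", "coding"),
                            classification = NULL) {
  sites <- match.arg(sites)
  rows <- which(aln$species == species)
  n <- length(rows)
  if (n < 2L)
    stop_sweepmk("sweepmk_sample_size_error",
                 "need >= 2 sequences of %s, got %d", species, n)
  cls <- classification %||% classify_sites(aln)
  clean <- which(apply(aln$seq, 2, function(col) all(col %in% BASES)))
  cols_used <- if (sites == "all") clean else cls$column + 1L
  if (!length(cols_used))
    stop_sweepmk("sweepmk_empty_data_error", "no retained columns")
  L <- length(cols_used)
  cls_of <- match(cols_used - 1L, cls$column)  # NA for non-codon columns
  pot <- if (nrow(cls)) count_potential_sites(aln, species = species,
                                              classification = cls)
         else list(L_syn = 0, L_nonsyn = 0)
  n_pairs <- n * (n - 1) / 2
  S <- 0L
  diff_tot <- 0; diff_syn <- 0; diff_non <- 0
  for (i in seq_along(cols_used)) {
    obs <- aln$seq[rows, cols_used[i]]
    tab <- table(obs)
    if (length(tab) < 2L) next
    S <- S + 1L
    ## pairwise differences at this column, split by substitution class in
    ## the reference codon context when the column sits in a codon
    states <- names(tab)
    cnt <- as.integer(tab)
    ci <- cls_of[i]
    for (a in seq_along(states)) for (b in seq_along(states)) {
      if (b <= a) next
      npair <- cnt[a] * cnt[b]
      diff_tot <- diff_tot + npair
      if (is.na(ci)) next
      cl <- substitution_class(cls$ref_codon[ci], cls$codon_pos[ci],
                               states[a], states[b])
      if (cl == "synonymous") diff_syn <- diff_syn + npair
      else diff_non <- diff_non + npair
    }
  }
  structure(list(
    S = S,
    theta_w = S / (harmonic_number(n - 1L) * L),
    pi_total = diff_tot / (n_pairs * L),
    pi_syn = if (pot$L_syn > 0) diff_syn / (n_pairs * pot$L_syn) else 0,
    pi_non = if (pot$L_nonsyn > 0) diff_non / (n_pairs * pot$L_nonsyn) else 0,
    n = n, L = L, L_syn = pot$L_syn, L_nonsyn = pot$L_nonsyn,
    locus_name = aln$locus_name, species = species
  ), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats %s [%s]: n=%d L=%d S=%d theta=%.4f pi=%.4f (syn %.4f, non %.4f)\n",
              x$locus_name, x$species, x$n, x$L, x$S, x$theta_w,
              x$pi_total, x$pi_syn, x$pi_non))
  invisible(x)
}

#' Construct a site-frequency-spectrum object
#'
#' @param counts Non-negative counts over derived-allele classes `1..n-1`
#'   (unfolded) or minor-allele classes `1..floor(n/2)` (folded).
#' @param n Haploid sample size.
#' @param site_class `"all"`, `"4-fold"` or `"0-fold"`.
#' @param polarized `TRUE` for an unfolded spectrum.
#' @return An `sfs`.
#' @export
new_sfs <- function(counts, n, site_class = "all", polarized = TRUE) {
  counts <- as.numeric(counts)
  nb <- if (polarized) n - 1L else n %/% 2L
  stopifnot(length(counts) == nb)
  structure(list(counts = counts, n = as.integer(n), site_class = site_class,
                 polarized = polarized), class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("%s SFS (n=%d, class=%s): S=%g\n",
              if (x$polarized) "unfolded" else "folded", x$n, x$site_class,
              sum(x$counts)))
  print(stats::setNames(x$counts, seq_along(x$counts)))
  invisible(x)
}

#' Fold an unfolded site-frequency spectrum
#' @param sfs An unfolded `sfs`.
#' @return The folded `sfs` (minor-allele counts 1..floor(n/2)).
#' @export
fold_sfs <- function(sfs) {
  if (!sfs$polarized) return(sfs)
  n <- sfs$n
  nb <- n %/% 2L
  folded <- numeric(nb)
  for (i in seq_len(n - 1L)) {
    j <- min(i, n - i)
    folded[j] <- folded[j] + sfs$counts[i]
  }
  new_sfs(folded, n, sfs$site_class, polarized = FALSE)
}

#' Site frequency spectrum of one species' sample
#'
#' Counts biallelic segregating sites by derived-allele copy number
#' (polarized against the outgroup) or minor-allele copy number (folded).
#' Multiallelic ingroup sites are excluded. For the polarized spectrum,
#' sites where the outgroup carries a state not among the two ingroup
#' alleles are dropped.
#'
#' @param aln A `locus_alignment`.
#' @param species Species tag to tabulate.
#' @param site_class `"all"`, `"4-fold"` or `"0-fold"` (fold class of the
#'   column).
#' @param polarize_with_outgroup If `TRUE` (default) return the unfolded
#'   spectrum using the outgroup consensus as the ancestral state.
#' @param classification Optional precomputed classification.
#' @return An `sfs`.
#' @export
compute_sfs <- function(aln, species, site_class = "all",
                        polarize_with_outgroup = TRUE,
                        classification = NULL) {
  rows <- which(aln$species == species)
  n <- length(rows)
  if (n < 2L)
    stop_sweepmk("sweepmk_sample_size_error", "need >= 2 sequences")
  out_rows <- which(aln$species == "outgroup")
  if (polarize_with_outgroup && !length(out_rows))
    stop_sweepmk("sweepmk_config_error",
                 "polarized SFS requested but alignment has no outgroup")
  cls <- classification %||% classify_sites(aln)
  keep <- if (site_class == "all") seq_len(nrow(cls)) else
    which(cls$fold_class == site_class)
  counts <- numeric(if (polarize_with_outgroup) n - 1L else n %/% 2L)
  for (i in keep) {
    col <- cls$column[i] + 1L
    obs <- aln$seq[rows, col]
    tab <- table(obs)
    if (length(tab) != 2L) next  # monomorphic or multiallelic
    if (polarize_with_outgroup) {
      anc <- consensus_base(aln$seq[out_rows, col])
      if (!(anc %in% names(tab))) next  # outgroup third state or ambiguous
      derived <- sum(obs != anc)
      if (derived >= 1L && derived <= n - 1L)
        counts[derived] <- counts[derived] + 1
    } else {
      mac <- min(tab)
      counts[min(mac, n - mac)] <- counts[min(mac, n - mac)] + 1
    }
  }
  new_sfs(counts, n, site_class, polarized = polarize_with_outgroup)
}

## Majority base among outgroup sequences; NA when tied or no clean base.
consensus_base <- function(bases) {
  bases <- bases[bases %in% BASES]
  if (!length(bases)) return(NA_character_)
  tab <- sort(table(bases), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2]) return(NA_character_)
  names(tab)[1]
}

#' Project an SFS to a smaller sample size
#'
#' Hypergeometric projection: each site with allele count i of n
#' contributes `P(j of m | i of n)` to bin j of the projected spectrum;
#' mass landing in bins 0 and m (monomorphic after projection) is
#' discarded. The default is the deterministic expectation; `mode =
#' "sample"` draws one hypergeometric realization per site, mirroring
#' literal random subsampling of alleles.
#'
#' @param sfs An `sfs`.
#' @param m Target sample size, `2 <= m <= n`.
#' @param mode `"expectation"` (default) or `"sample"`.
#' @param seed Integer seed, required for `mode = "sample"`.
#' @return The projected `sfs` at sample size `m`.
#' @export
project_sfs <- function(sfs, m, mode = c("expectation", "sample"),
                        seed = NULL) {
  mode <- match.arg(mode)
  n <- sfs$n
  if (m > n || m < 2L)
    stop_sweepmk("sweepmk_projection_error",
                 "projection size m=%d outside 2..n=%d", m, n)
  if (m == n) return(sfs)
  proj_one <- function(i) stats::dhyper(0:m, i, n - i, m)
  if (sfs$polarized) {
    out <- numeric(m - 1L)
    for (i in seq_len(n - 1L)) {
      ci <- sfs$counts[i]
      if (ci == 0) next
      if (mode == "expectation") {
        p <- proj_one(i)
        out <- out + ci * p[2:m]
      } else {
        draws <- with_seed(derive_seed(seed %||% 1L, i),
                           stats::rhyper(ci, i, n - i, m))
        tab <- tabulate(draws[draws >= 1 & draws <= m - 1], nbins = m - 1L)
        out <- out + tab
      }
    }
    new_sfs(out, m, sfs$site_class, polarized = TRUE)
  } else {
    ## minor-allele counts: project as if derived, then fold the result
    nb <- m %/% 2L
    out <- numeric(nb)
    for (i in seq_len(n %/% 2L)) {
      ci <- sfs$counts[i]
      if (ci == 0) next
      p <- proj_one(i)
      for (j in seq_len(m - 1L)) {
        jj <- min(j, m - j)
        out[jj] <- out[jj] + ci * p[j + 1L]
      }
    }
    new_sfs(out, m, sfs$site_class, polarized = FALSE)
  }
}
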