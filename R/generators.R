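## Synthetic-data generators: codon alignments with planted MK composition,
## sweep-distorted SFS samples, and toy outlier-interval universes.

#' Generate a codon alignment with a planted MK table
#'
#' Builds an alignment of `codons` glycine (GGG) codons for two ingroups
#' plus one outgroup and plants exactly the requested synonymous /
#' nonsynonymous polymorphisms and fixed differences, one event per
#' randomly chosen codon: synonymous events at the 4-fold third position
#' (GGG/GGA), nonsynonymous at the 0-fold first position (GGG/AGG).
#' Round-trip guarantee: `build_mk_table()` on the result recovers
#' `target` exactly.
#'
#' @param target An `mk_table` (or vector `c(P_s, D_s, P_n, D_n)`).
#' @param n1,n2 Ingroup sample sizes (each `>= 2`).
#' @param codons Alignment length in codons; must hold all events.
#' @param seed Integer seed.
#' @return A `locus_alignment`.
#' @export
generate_mk_alignment <- function(target, n1 = 6L, n2 = 6L, codons = 500L,
                                  seed = 1L) {
  if (!inherits(target, "mk_table"))
    target <- mk_table(target[1], target[2], target[3], target[4])
  n_events <- target$syn_poly + target$syn_div + target$nonsyn_poly +
    target$nonsyn_div
  if (n_events > codons)
    stop_sweepmk("sweepmk_generation_error",
                 "%d events exceed %d available codons", n_events, codons)
  if (n1 < 2L || n2 < 2L)
    stop_sweepmk("sweepmk_config_error", "ingroup sample sizes must be >= 2")
  with_seed(seed, {
    n_seq <- n1 + n2 + 1L
    base <- matrix(rep(c("G", "G", "G"), codons), n_seq, 3L * codons,
                   byrow = TRUE)
    rows1 <- seq_len(n1); rows2 <- n1 + seq_len(n2)
    ev_codons <- sample.int(codons, n_events)
    k <- 0L
    plant <- function(type) {
      for (dummy in seq_len(switch(type,
                                   sp = target$syn_poly, sd = target$syn_div,
                                   np = target$nonsyn_poly,
                                   nd = target$nonsyn_div))) {
        k <<- k + 1L
        cod <- ev_codons[k]
        pos <- if (type %in% c("sp", "sd")) 3L else 1L
        alt <- "A"  # GGG -> GGA (syn, 3rd) or GGG -> AGG (nonsyn, 1st)
        col <- 3L * (cod - 1L) + pos
        if (type %in% c("sp", "np")) {
          ing <- if (stats::runif(1) < 0.5) rows1 else rows2
          carriers <- sample(ing, sample(seq_len(length(ing) - 1L), 1L))
          base[carriers, col] <<- alt
        } else {
          fixed_in <- if (stats::runif(1) < 0.5) rows1 else rows2
          base[fixed_in, col] <<- alt
        }
      }
    }
    plant("sp"); plant("sd"); plant("np"); plant("nd")
    rownames(base) <- c(paste0("m", seq_len(n1)), paste0("s", seq_len(n2)),
                        "out1")
    locus_alignment(base,
                    c(rep("ingroup1", n1), rep("ingroup2", n2), "outgroup"),
                    locus_name = target$locus_name)
  })
}

#' Sample segregating-site frequencies from a sweep-distorted spectrum
#'
#' @param phi A `background_sfs`.
#' @param alpha_s,d Sweep intensity and distance (see [sweep_spectrum()]).
#' @param n_sites Number of segregating sites to draw.
#' @param seed Integer seed.
#' @return An unfolded `sfs` of the drawn counts.
#' @export
sample_sweep_sfs <- function(phi, alpha_s, d, n_sites, seed = 1L) {
  p <- sweep_spectrum(phi, alpha_s, d)
  with_seed(seed, {
    draws <- sample.int(phi$n - 1L, n_sites, replace = TRUE, prob = p)
    new_sfs(tabulate(draws, nbins = phi$n - 1L), phi$n)
  })
}

#' Generate a toy genome of candidate loci and outlier intervals
#'
#' Random non-overlapping outlier intervals and random candidate locus
#' intervals with chromosome labels over a toy three-chromosome genome,
#' reproducible under the seed.
#'
#' @param n_loci Number of candidate loci.
#' @param chrom_weights Named sampling weights for chromosomes
#'   (default X/2/3 equal).
#' @param genome_bp Length of each chromosome (bp).
#' @param n_outlier_intervals,interval_bp Outlier interval count and width.
#' @param locus_bp Width of each candidate locus interval.
#' @param seed Integer seed.
#' @return List with data frames `loci` (`name`, `chrom`, `start`, `end`)
#'   and `outliers` (`chrom`, `start`, `end`), 0-based half-open.
#' @export
generate_outlier_universe <- function(n_loci, chrom_weights = c(X = 1, `2` = 1, `3` = 1),
                                      genome_bp = 1e6, n_outlier_intervals = 10L,
                                      interval_bp = 2e4, locus_bp = 2000L,
                                      seed = 1L) {
  chroms <- names(chrom_weights)
  with_seed(seed, {
    ## non-overlapping outliers by bounded rejection sampling per chromosome
    out <- list()
    if (n_outlier_intervals > 0L) {
      oc <- sample(chroms, n_outlier_intervals, replace = TRUE,
                   prob = chrom_weights)
      for (ch in unique(oc)) {
        m <- sum(oc == ch)
        if (m * interval_bp > genome_bp)
          stop_sweepmk("sweepmk_generation_error",
                       "cannot pack %d x %d bp intervals into %g bp", m,
                       interval_bp, genome_bp)
        starts <- numeric(0)
        for (tries in seq_len(1000L)) {
          cand <- floor(stats::runif(1, 0, genome_bp - interval_bp))
          if (!any(abs(cand - starts) < interval_bp)) {
            starts <- c(starts, cand)
            if (length(starts) == m) break
          }
        }
        if (length(starts) < m)
          stop_sweepmk("sweepmk_generation_error",
                       "failed to place non-overlapping intervals on %s", ch)
        out[[ch]] <- data.frame(chrom = ch, start = sort(starts),
                                end = sort(starts) + interval_bp)
      }
    }
    outliers <- if (length(out)) do.call(rbind, out) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    rownames(outliers) <- NULL
    lc <- sample(chroms, n_loci, replace = TRUE, prob = chrom_weights)
    ls <- floor(stats::runif(n_loci, 0, genome_bp - locus_bp))
    loci <- data.frame(name = paste0("locus", seq_len(n_loci)), chrom = lc,
                       start = ls, end = ls + locus_bp,
                       stringsAsFactors = FALSE)
    list(loci = loci, outliers = outliers)
  })
}

#' Write intervals as BED (0-based half-open)
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  df <- intervals[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED path (first three or four columns used).
#' @return Data frame with `chrom`, `start`, `end` (and `name` if present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "name"
  df$chrom <- as.character(df$chrom)
  df[, intersect(c("chrom", "start", "end", "name"), names(df))]
}
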