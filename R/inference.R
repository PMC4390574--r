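## Multiple-testing correction with the study's family structure and the
## chromosome-matched bootstrap overlap test.

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @param q FDR level for the rejection flags (default 0.05).
#' @return List with `adjusted` (same order as input) and `reject`
#'   (`adjusted <= q`).
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  if (!length(pvalues))
    stop_sweepmk("sweepmk_config_error", "empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_sweepmk("sweepmk_config_error", "p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Grouped FDR correction of a p-value set
#'
#' Applies BH within four families: SFS-dependent tests (sweed + mk)
#' per species, and the LD-based omega test per species — the spectrum
#' and count based tests share information, LD does not.
#'
#' @param pset Data frame with columns `gene_region`, `species`, `test`
#'   (`"sweed"`, `"omega"`, `"mk"`), `demographic_scenario`, `p_raw`.
#' @param q FDR level (default 0.05).
#' @return The data frame with `family`, `p_adj` and `significant` added.
#' @export
group_and_adjust <- function(pset, q = 0.05) {
  need <- c("gene_region", "species", "test", "p_raw")
  if (!all(need %in% names(pset)))
    stop_sweepmk("sweepmk_config_error", "p-value set lacks columns: %s",
                 paste(setdiff(need, names(pset)), collapse = ", "))
  if (!all(pset$test %in% c("sweed", "omega", "mk")))
    stop_sweepmk("sweepmk_classification_error", "unknown test label(s): %s",
                 paste(setdiff(pset$test, c("sweed", "omega", "mk")),
                       collapse = ", "))
  pset$family <- ifelse(pset$test == "omega",
                        paste0("omega|", pset$species),
                        paste0("sfs|", pset$species))
  pset$p_adj <- NA_real_
  for (fam in unique(pset$family)) {
    idx <- which(pset$family == fam & !is.na(pset$p_raw))
    if (length(idx))
      pset$p_adj[idx] <- bh_adjust(pset$p_raw[idx], q)$adjusted
  }
  pset$significant <- !is.na(pset$p_adj) & pset$p_adj <= q
  pset
}

## boundary distance between two half-open intervals on the same
## chromosome; 0 when they overlap or touch
interval_distance <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s2 - e1, s1 - e2))
}

count_near_outliers <- function(loci, outliers, distance_bp) {
  if (!nrow(outliers)) return(0L)
  hits <- 0L
  for (i in seq_len(nrow(loci))) {
    same <- outliers[outliers$chrom == loci$chrom[i], , drop = FALSE]
    if (!nrow(same)) next
    d <- interval_distance(loci$start[i], loci$end[i], same$start, same$end)
    if (any(d <= distance_bp)) hits <- hits + 1L
  }
  hits
}

#' Chromosome-matched bootstrap test of outlier overlap
#'
#' Counts how many study loci fall within `distance_bp` of an outlier
#' interval (boundary-to-boundary; overlap counts as distance 0, and a
#' locus at exactly `distance_bp` counts as within). Each of `n_draws`
#' bootstrap draws samples, without replacement, the same number of loci
#' per chromosome from the candidate universe;
#' `p = #\{draws >= observed\} / n_draws` (no add-one correction,
#' following the genome-wide resampling convention).
#'
#' @param loci Data frame of study loci (`chrom`, `start`, `end`).
#' @param outliers Data frame of outlier intervals (`chrom`, `start`,
#'   `end`).
#' @param universe Data frame of candidate loci to resample from.
#' @param n_draws Number of bootstrap draws (default 1000).
#' @param distance_bp Distance threshold in bp (default 0 = overlap only).
#' @param seed Integer seed.
#' @return An `overlap_test` list: `observed`, `n_draws`,
#'   `n_at_least_observed`, `p_value`, `draw_counts`.
#' @export
bootstrap_overlap <- function(loci, outliers, universe, n_draws = 1000L,
                              distance_bp = 0, seed = 1L) {
  chrom_counts <- table(loci$chrom)
  for (ch in names(chrom_counts))
    if (sum(universe$chrom == ch) < chrom_counts[[ch]])
      stop_sweepmk("sweepmk_sampling_error",
                   "universe has %d loci on chromosome %s, need %d",
                   sum(universe$chrom == ch), ch, chrom_counts[[ch]])
  observed <- count_near_outliers(loci, outliers, distance_bp)
  draws <- with_seed(seed, {
    vapply(seq_len(n_draws), function(b) {
      pick <- do.call(rbind, lapply(names(chrom_counts), function(ch) {
        pool <- universe[universe$chrom == ch, , drop = FALSE]
        pool[sample.int(nrow(pool), chrom_counts[[ch]]), , drop = FALSE]
      }))
      count_near_outliers(pick, outliers, distance_bp)
    }, integer(1))
  })
  n_ge <- sum(draws >= observed)
  structure(list(observed = observed, n_draws = n_draws,
                 n_at_least_observed = n_ge, p_value = n_ge / n_draws,
                 draw_counts = draws), class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("bootstrap overlap: observed %d; %d of %d draws >= observed (p = %.3f)\n",
              x$observed, x$n_at_least_observed, x$n_draws, x$p_value))
  invisible(x)
}
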