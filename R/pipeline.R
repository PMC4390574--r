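## End-to-end orchestration: alignments -> summaries -> MK -> sweep/omega
## scans against simulated nulls -> grouped FDR -> optional bootstrap
## overlap, with deterministic TSV/JSON reports.

#' Extract one species' haplotypes from a coding alignment
#'
#' Biallelic retained columns become 0/1 sites; with an outgroup the
#' derived allele is the one differing from the outgroup consensus
#' (columns with an outgroup third state are dropped), otherwise the
#' minor allele is coded 1 and downstream scans should run folded.
#'
#' @param aln A `locus_alignment`.
#' @param species Species tag to extract.
#' @param polarize Use the outgroup to orient alleles (default `TRUE`
#'   when an outgroup is present).
#' @param classification Optional precomputed classification.
#' @return A `haplotype_matrix` whose positions are alignment columns
#'   (bp = columns; `locus_length_bp` = alignment width).
#' @export
haplotypes_from_alignment <- function(aln, species,
                                      polarize = any(aln$species == "outgroup"),
                                      classification = NULL) {
  rows <- which(aln$species == species)
  if (length(rows) < 2L)
    stop_sweepmk("sweepmk_sample_size_error", "need >= 2 sequences")
  out_rows <- which(aln$species == "outgroup")
  if (polarize && !length(out_rows))
    stop_sweepmk("sweepmk_config_error", "polarization requested without outgroup")
  cls <- classification %||% classify_sites(aln)
  L <- ncol(aln$seq)
  cols <- integer(0); carriers <- list()
  for (i in seq_len(nrow(cls))) {
    col <- cls$column[i] + 1L
    obs <- aln$seq[rows, col]
    tab <- table(obs)
    if (length(tab) != 2L) next
    if (polarize) {
      anc <- consensus_base(aln$seq[out_rows, col])
      if (is.na(anc) || !(anc %in% names(tab))) next
      derived <- obs != anc
    } else {
      minor <- names(tab)[which.min(tab)]
      derived <- obs == minor
    }
    cols <- c(cols, col - 1L)
    carriers[[length(carriers) + 1L]] <- which(derived)
  }
  mat <- matrix(0L, length(rows), length(cols))
  for (j in seq_along(cols)) mat[carriers[[j]], j] <- 1L
  structure(list(mat = mat, positions = cols / L, n = length(rows),
                 locus_length_bp = as.integer(L)),
            class = "haplotype_matrix")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("sweepmk_pipeline_error", "sweepmk_error",
                             "error", "condition"),
                   list(message = sprintf("stage '%s': %s", stage,
                                          conditionMessage(e)),
                        call = NULL, stage = stage)))
  })
}

#' Run the full multi-test selection pipeline
#'
#' Stages: site classification, per-species polymorphism summaries, MK
#' tests (segments of one gene summed), CLR and omega scans judged
#' against coalescent nulls under the configured demographic scenarios,
#' grouped BH correction, and an optional chromosome-matched bootstrap
#' against outlier intervals. Reports are written as TSV plus a JSON
#' summary; identical config and seed give byte-identical files.
#'
#' @param config A list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{loci}{list of locus entries: either `alignment` (a
#'       `locus_alignment`) or `fasta` + `species_map` (+
#'       `frame_offset`, `chromosome`, `segment_id`); optional `gene`
#'       groups segments for the MK stage.}
#'     \item{priors}{named list per species tag of prior ranges, each a
#'       list like `list(theta_per_site = c(0.006, 0.009))`.}
#'     \item{scenarios}{demographic scenario kinds to simulate (default
#'       `"constant"`).}
#'     \item{n_sims}{null replicates per scan (default 200).}
#'     \item{scans}{run the sweep scans? (default `TRUE`)}
#'     \item{polarize}{polarize with the outgroup (default `TRUE`).}
#'     \item{outliers,universe}{optional interval data frames (or BED
#'       paths) for the bootstrap overlap stage; `distance_bp`
#'       (default 0), `n_draws` (default 1000).}
#'     \item{fdr_q}{FDR level (default 0.05).}
#'     \item{seed}{integer master seed (default 1).}
#'     \item{out_dir}{report directory (required).}
#'   }
#' @return Invisibly, a list with `sumstats`, `mk`, `pvalues` (the
#'   adjusted p-value set), `overlap`, and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||%
    stop_sweepmk("sweepmk_config_error", "config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  scenarios <- config$scenarios %||% "constant"
  n_sims <- config$n_sims %||% 200L
  q <- config$fdr_q %||% 0.05
  do_scans <- config$scans %||% TRUE
  polarize <- config$polarize %||% TRUE

  loci <- pipeline_stage("read", {
    lapply(config$loci, function(entry) {
      aln <- entry$alignment %||% read_fasta_alignment(
        entry$fasta, entry$species_map,
        frame_offset = entry$frame_offset %||% 0L,
        chromosome = entry$chromosome %||% "other",
        segment_id = entry$segment_id)
      list(aln = aln, gene = entry$gene %||% aln$locus_name)
    })
  })

  cls_list <- pipeline_stage("classify",
    lapply(loci, function(l) classify_sites(l$aln)))

  species_of <- function(aln) intersect(c("ingroup1", "ingroup2"),
                                        unique(aln$species))

  stats_tab <- pipeline_stage("sumstats", {
    rows <- list()
    for (i in seq_along(loci)) {
      for (sp in species_of(loci[[i]]$aln)) {
        st <- summarize_locus(loci[[i]]$aln, sp,
                              classification = cls_list[[i]])
        rows[[length(rows) + 1L]] <- data.frame(
          locus = loci[[i]]$aln$locus_name, species = sp, n = st$n,
          S = st$S, theta = st$theta_w, pi_tot = st$pi_total,
          pi_syn = st$pi_syn, pi_non = st$pi_non)
      }
    }
    do.call(rbind, rows)
  })

  mk_tab <- pipeline_stage("mk", {
    genes <- unique(vapply(loci, `[[`, character(1), "gene"))
    rows <- list(); results <- list()
    for (g in genes) {
      idx <- which(vapply(loci, `[[`, character(1), "gene") == g)
      ## segments of one gene summed = concatenation for counting purposes
      parts <- lapply(idx, function(i)
        build_mk_table(loci[[i]]$aln, classification = cls_list[[i]]))
      tab <- mk_table(sum(vapply(parts, `[[`, integer(1), "syn_poly")),
                      sum(vapply(parts, `[[`, integer(1), "syn_div")),
                      sum(vapply(parts, `[[`, integer(1), "nonsyn_poly")),
                      sum(vapply(parts, `[[`, integer(1), "nonsyn_div")),
                      locus_name = g)
      res <- tryCatch(mk_test(tab), sweepmk_undefined_test_error =
                        function(e) NULL)
      results[[g]] <- list(table = tab, result = res)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, syn_poly = tab$syn_poly, syn_div = tab$syn_div,
        nonsyn_poly = tab$nonsyn_poly, nonsyn_div = tab$nonsyn_div,
        p_value = if (is.null(res)) NA_real_ else res$p_value)
    }
    list(table = do.call(rbind, rows), results = results)
  })

  pvals <- list()
  for (g in unique(mk_tab$table$gene)) {
    pg <- mk_tab$table$p_value[mk_tab$table$gene == g][1]
    ## the pooled MK p enters each species' SFS family
    for (sp in c("ingroup1", "ingroup2"))
      pvals[[length(pvals) + 1L]] <- data.frame(
        gene_region = g, species = sp, test = "mk",
        demographic_scenario = NA_character_, p_raw = pg)
  }

  if (isTRUE(do_scans)) pipeline_stage("scans", {
    for (i in seq_along(loci)) {
      aln <- loci[[i]]$aln
      for (sp in species_of(aln)) {
        hm <- haplotypes_from_alignment(aln, sp, polarize = polarize,
                                        classification = cls_list[[i]])
        prior <- (config$priors %||% list())[[sp]] %||%
          list(theta_per_site = c(0.005, 0.02))
        run_scan <- function(stat) {
          obs <- tryCatch(
            if (stat == "max_CLR") clr_scan(hm, folded = !polarize)$max_CLR
            else omega_max(hm)$max_omega,
            sweepmk_error = function(e) NA_real_)
          if (is.na(obs)) return(NULL)
          for (sc in scenarios) {
            nd <- null_distribution(
              stat, prior, demography_kind = sc, n = hm$n,
              locus_length = hm$locus_length_bp, n_sims = n_sims,
              seed = derive_seed(seed, 1000L * i +
                                   100L * match(sp, SPECIES_TAGS) +
                                   10L * match(sc, scenarios) +
                                   (stat == "max_omega")),
              scan_args = if (stat == "max_CLR")
                list(folded = !polarize) else list())
            pvals[[length(pvals) + 1L]] <<- data.frame(
              gene_region = aln$locus_name, species = sp,
              test = if (stat == "max_CLR") "sweed" else "omega",
              demographic_scenario = sc,
              p_raw = empirical_pvalue(obs, nd))
          }
        }
        run_scan("max_CLR")
        run_scan("max_omega")
      }
    }
  })

  pset <- pipeline_stage("fdr", {
    df <- do.call(rbind, pvals)
    group_and_adjust(df[!is.na(df$p_raw) | df$test == "mk", ], q = q)
  })

  overlap <- NULL
  if (!is.null(config$outliers) && !is.null(config$loci_intervals) &&
      !is.null(config$universe)) {
    overlap <- pipeline_stage("bootstrap_overlap", {
      get_df <- function(x) if (is.character(x)) read_bed(x) else x
      bootstrap_overlap(get_df(config$loci_intervals),
                        get_df(config$outliers), get_df(config$universe),
                        n_draws = config$n_draws %||% 1000L,
                        distance_bp = config$distance_bp %||% 0,
                        seed = derive_seed(seed, 99L))
    })
  }

  paths <- pipeline_stage("report", {
    write_tsv <- function(df, name) {
      p <- file.path(out_dir, name)
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(x) signif(x, 10))
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    p2 <- write_tsv(stats_tab, "summary_stats.tsv")
    mk_out <- mk_tab$table
    adj1 <- pset[pset$test == "mk" & pset$species == "ingroup1", ]
    mk_out$p_adj <- adj1$p_adj[match(mk_out$gene, adj1$gene_region)]
    p4 <- write_tsv(mk_out, "mk_tests.tsv")
    p3 <- write_tsv(pset, "pvalues.tsv")
    summary <- list(
      seed = seed, n_loci = length(loci), scenarios = scenarios,
      n_sims = n_sims,
      mk = stats::setNames(as.list(signif(mk_tab$table$p_value, 10)),
                           mk_tab$table$gene),
      n_significant = sum(pset$significant, na.rm = TRUE),
      overlap = if (!is.null(overlap))
        list(observed = overlap$observed, p_value = overlap$p_value))
    pj <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, pj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    list(summary_stats = p2, mk_tests = p4, pvalues = p3, summary = pj)
  })

  invisible(list(sumstats = stats_tab, mk = mk_tab, pvalues = pset,
                 overlap = overlap, paths = paths))
}
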