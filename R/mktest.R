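## McDonald-Kreitman 2x2 tables, tests, neutrality index, alpha and
## Nei-Gojobori dN/dS between species.

#' Construct an MK 2x2 count table
#' @param syn_poly,syn_div,nonsyn_poly,nonsyn_div Non-negative integer
#'   counts (P_s, D_s, P_n, D_n).
#' @param locus_name Label.
#' @return An `mk_table`.
#' @export
mk_table <- function(syn_poly, syn_div, nonsyn_poly, nonsyn_div,
                     locus_name = "locus") {
  v <- c(syn_poly, syn_div, nonsyn_poly, nonsyn_div)
  if (any(v < 0) || any(v != round(v)))
    stop_sweepmk("sweepmk_config_error", "MK counts must be non-negative integers")
  structure(list(syn_poly = as.integer(syn_poly), syn_div = as.integer(syn_div),
                 nonsyn_poly = as.integer(nonsyn_poly),
                 nonsyn_div = as.integer(nonsyn_div),
                 locus_name = locus_name), class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  m <- matrix(c(x$syn_poly, x$syn_div, x$nonsyn_poly, x$nonsyn_div), 2, 2,
              byrow = TRUE,
              dimnames = list(c("synonymous", "nonsynonymous"),
                              c("polymorphic", "divergent")))
  cat(sprintf("mk_table '%s'\n", x$locus_name)); print(m)
  invisible(x)
}

#' Build an MK table from a two-ingroup alignment with outgroup
#'
#' A retained coding column is counted as polymorphic if it segregates
#' within either ingroup (pooled across species, counted once), and as a
#' fixed difference if both ingroups are monomorphic with different
#' states. Each counted column is classified synonymous or nonsynonymous
#' in its codon context; for codons varying at more than one position the
#' context for each varying column takes the outgroup-matching
#' (parsimonious) state at the other positions, falling back to the
#' majority state (`multi_hit = "resolve"`), or the whole codon is
#' dropped (`multi_hit = "exclude"`).
#'
#' @param aln A `locus_alignment` containing both ingroups and an outgroup.
#' @param multi_hit Policy for codons with more than one varying position.
#' @param classification Optional precomputed classification.
#' @return An `mk_table`.
#' @export
build_mk_table <- function(aln, multi_hit = c("resolve", "exclude"),
                           classification = NULL) {
  multi_hit <- match.arg(multi_hit)
  for (tag in SPECIES_TAGS)
    if (!any(aln$species == tag))
      stop_sweepmk("sweepmk_config_error", "alignment lacks %s sequences", tag)
  cls <- classification %||% classify_sites(aln)
  rows1 <- which(aln$species == "ingroup1")
  rows2 <- which(aln$species == "ingroup2")
  rows_out <- which(aln$species == "outgroup")
  Ps <- 0L; Ds <- 0L; Pn <- 0L; Dn <- 0L
  for (ci in unique(cls$codon_index)) {
    sub <- cls[cls$codon_index == ci, , drop = FALSE]
    cols <- sub$column + 1L
    status <- character(3)   # per position: none/poly/fixed
    pair <- vector("list", 3)
    for (p in 1:3) {
      s1 <- unique(aln$seq[rows1, cols[p]])
      s2 <- unique(aln$seq[rows2, cols[p]])
      if (length(s1) > 1L || length(s2) > 1L) {
        status[p] <- "poly"
        pair[[p]] <- unique(c(s1, s2))
      } else if (s1 != s2) {
        status[p] <- "fixed"
        pair[[p]] <- c(s1, s2)
      } else status[p] <- "none"
    }
    varying <- which(status != "none")
    if (!length(varying)) next
    if (length(varying) > 1L && multi_hit == "exclude") next
    out_cod <- vapply(1:3, function(p) consensus_base(aln$seq[rows_out, cols[p]]),
                      character(1))
    maj_cod <- strsplit(sub$ref_codon[1], "")[[1]]
    for (p in varying) {
      st <- pair[[p]]
      if (length(st) > 2L) next  # multiallelic column: skip classification
      ## codon context: other positions from outgroup where clean, else
      ## majority reference codon
      ctx <- maj_cod
      repl <- !is.na(out_cod)
      ctx[repl] <- out_cod[repl]
      ctx[p] <- maj_cod[p]
      cl <- substitution_class(paste(ctx, collapse = ""), p, st[1], st[2])
      if (status[p] == "poly") {
        if (cl == "synonymous") Ps <- Ps + 1L else Pn <- Pn + 1L
      } else {
        if (cl == "synonymous") Ds <- Ds + 1L else Dn <- Dn + 1L
      }
    }
  }
  mk_table(Ps, Ds, Pn, Dn, locus_name = aln$locus_name)
}

#' McDonald-Kreitman test on a 2x2 table
#'
#' Tests independence of the synonymous/nonsynonymous x
#' polymorphic/divergent table. `"chi2"` is a Pearson chi-square with 1 df
#' and no continuity correction; `"g"` the likelihood-ratio G-test;
#' `"fisher"` the two-sided exact test. Also returns the neutrality index
#' `NI = (P_n/P_s)/(D_n/D_s)` and `alpha_mk = 1 - NI`.
#'
#' @param table An `mk_table`.
#' @param method `"chi2"` (default), `"g"` or `"fisher"`.
#' @return An `mk_result` list: `p_value`, `statistic`, `method`,
#'   `neutrality_index`, `alpha_mk`, `table`.
#' @export
mk_test <- function(table, method = c("chi2", "g", "fisher")) {
  method <- match.arg(method)
  m <- matrix(c(table$syn_poly, table$syn_div,
                table$nonsyn_poly, table$nonsyn_div), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_sweepmk("sweepmk_undefined_test_error",
                 "MK test undefined: zero margin in table '%s'",
                 table$locus_name)
  if (method == "chi2") {
    ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    stat <- unname(ht$statistic); p <- ht$p.value
  } else if (method == "g") {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    terms <- ifelse(m > 0, m * log(m / e), 0)
    stat <- 2 * sum(terms)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    ht <- stats::fisher.test(m)
    stat <- NA_real_; p <- ht$p.value
  }
  ni <- if (table$syn_poly > 0 && table$nonsyn_div > 0 && table$syn_div > 0)
    (table$nonsyn_poly / table$syn_poly) / (table$nonsyn_div / table$syn_div)
  else NA_real_
  structure(list(p_value = p, statistic = stat, method = method,
                 neutrality_index = ni,
                 alpha_mk = if (is.na(ni)) NA_real_ else 1 - ni,
                 table = table), class = "mk_result")
}

#' @export
print.mk_result <- function(x, ...) {
  cat(sprintf("MK test (%s) '%s': p = %.4g, NI = %.3f, alpha = %.3f\n",
              x$method, x$table$locus_name, x$p_value,
              x$neutrality_index, x$alpha_mk))
  invisible(x)
}

## Nei-Gojobori codon-pair difference counts: average synonymous and
## nonsynonymous differences over all minimum-length pathways between two
## codons (pathways through stop codons dropped when alternatives exist).
ng_codon_diffs <- function(cod_a, cod_b) {
  ct <- codon_tables()
  a <- strsplit(cod_a, "")[[1]]; b <- strsplit(cod_b, "")[[1]]
  pos <- which(a != b)
  d <- length(pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- if (d == 1L) list(pos) else {
    perms <- if (d == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(o) pos[o])
    }
    perms
  }
  evals <- lapply(paths, function(ord) {
    cur <- a; syn <- 0; non <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      ca <- paste(cur, collapse = ""); cb <- paste(nxt, collapse = "")
      if (ct$aa[[cb]] == "*" && !identical(nxt, b)) ok <- FALSE
      if (ct$aa[[ca]] == ct$aa[[cb]]) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    list(syn = syn, nonsyn = non, ok = ok)
  })
  valid <- Filter(function(e) e$ok, evals)
  if (!length(valid)) valid <- evals
  c(syn = mean(vapply(valid, `[[`, numeric(1), "syn")),
    nonsyn = mean(vapply(valid, `[[`, numeric(1), "nonsyn")))
}

#' Pairwise dN/dS between two species (Nei-Gojobori, Jukes-Cantor corrected)
#'
#' Compares one representative sequence per species (the majority
#' consensus by default) codon by codon; multi-hit codons are averaged
#' over minimum-length mutational pathways. Proportions are corrected with
#' `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param aln A `locus_alignment`.
#' @param species_a,species_b Species tags to compare.
#' @param representative `"consensus"` (default) or `"first"`.
#' @return A `dnds_result` list: `dN`, `dS`, `ratio`, `N_d`, `S_d`,
#'   `L_syn`, `L_nonsyn`.
#' @export
pairwise_dnds <- function(aln, species_a = "ingroup1", species_b = "ingroup2",
                          representative = c("consensus", "first")) {
  representative <- match.arg(representative)
  cls <- classify_sites(aln)
  starts <- unique(cls$column[cls$codon_pos == 1L])
  if (!length(starts))
    stop_sweepmk("sweepmk_empty_data_error", "no retained codons")
  get_seq <- function(tag) {
    rows <- which(aln$species == tag)
    if (!length(rows))
      stop_sweepmk("sweepmk_config_error", "no sequences for %s", tag)
    if (representative == "first" || length(rows) == 1L)
      return(aln$seq[rows[1L], ])
    apply(aln$seq[rows, , drop = FALSE], 2, function(col) {
      cb <- consensus_base(col); if (is.na(cb)) sort(col)[1] else cb
    })
  }
  sa <- get_seq(species_a); sb <- get_seq(species_b)
  ct <- codon_tables()
  Sd <- 0; Nd <- 0; Ls <- 0
  for (s in starts) {
    ca <- paste(sa[(s + 1L):(s + 3L)], collapse = "")
    cb <- paste(sb[(s + 1L):(s + 3L)], collapse = "")
    dd <- ng_codon_diffs(ca, cb)
    Sd <- Sd + dd["syn"]; Nd <- Nd + dd["nonsyn"]
    Ls <- Ls + (sum(ct$syn_frac[ca, ]) + sum(ct$syn_frac[cb, ])) / 2
  }
  Ltot <- 3 * length(starts); Ln <- Ltot - Ls
  pS <- Sd / Ls; pN <- Nd / Ln
  jc <- function(p) {
    if (p >= 0.75)
      stop_sweepmk("sweepmk_saturation_error",
                   "proportion of differences %.3f >= 3/4: JC correction undefined", p)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(unname(pS)); dN <- jc(unname(pN))
  structure(list(dN = dN, dS = dS,
                 ratio = if (dS > 0) dN / dS else Inf,
                 N_d = unname(Nd), S_d = unname(Sd),
                 L_syn = unname(Ls), L_nonsyn = unname(Ln)),
            class = "dnds_result")
}
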