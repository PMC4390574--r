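## Codon-aware handling of coding alignments: reading/validation, degeneracy
## classification and Nei-Gojobori potential-site counting.

BASES <- c("A", "C", "G", "T")
ALLOWED_CHARS <- c(BASES, "-", "N")
SPECIES_TAGS <- c("ingroup1", "ingroup2", "outgroup")

.codon_env <- new.env(parent = emptyenv())

## Lazy per-codon lookup tables built from the standard genetic code:
## amino acid per codon, per-position synonymous one-step fraction, and
## per-position count of synonymous alternatives (degeneracy).
codon_tables <- function() {
  if (!is.null(.codon_env$aa)) return(as.list(.codon_env))
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  syn_frac <- matrix(0, length(codons), 3, dimnames = list(codons, NULL))
  n_syn_alt <- matrix(0L, length(codons), 3, dimnames = list(codons, NULL))
  for (cod in codons) {
    cs <- strsplit(cod, "")[[1]]
    for (p in 1:3) {
      alts <- setdiff(BASES, cs[p])
      syn <- vapply(alts, function(b) {
        alt <- cs; alt[p] <- b
        gc_tab[[paste(alt, collapse = "")]] == gc_tab[[cod]]
      }, logical(1))
      n_syn_alt[cod, p] <- sum(syn)
      syn_frac[cod, p] <- sum(syn) / 3
    }
  }
  .codon_env$aa <- gc_tab
  .codon_env$syn_frac <- syn_frac
  .codon_env$n_syn_alt <- n_syn_alt
  .codon_env$stops <- codons[gc_tab == "*"]
  as.list(.codon_env)
}

#' Construct a validated coding-locus alignment
#'
#' A `locus_alignment` holds aligned coding sequences for up to three
#' species roles: two ingroups (the polymorphism samples) and an outgroup
#' used for polarization and divergence orientation.
#'
#' @param sequences Named character vector of aligned sequences
#'   (names are sample ids), or a character matrix with one row per sample.
#' @param species Character vector mapping each sample to one of
#'   `"ingroup1"`, `"ingroup2"`, `"outgroup"`; recycled names must match
#'   `sequences`.
#' @param locus_name Locus label.
#' @param chromosome One of `"X"`, `"2"`, `"3"`, `"other"`.
#' @param frame_offset 0-based column of the first complete codon.
#' @param segment_id Optional amplicon/segment label (e.g. `"pum 3"`).
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(sequences, species, locus_name = "locus",
                            chromosome = c("other", "X", "2", "3"),
                            frame_offset = 0L, segment_id = NULL) {
  chromosome <- match.arg(chromosome)
  if (is.matrix(sequences)) {
    mat <- toupper(sequences)
  } else {
    seqs <- toupper(as.character(sequences))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop_sweepmk("sweepmk_alignment_error",
                   "aligned sequences differ in length (%s)",
                   paste(unique(lens), collapse = ", "))
    mat <- do.call(rbind, strsplit(seqs, ""))
    rownames(mat) <- names(sequences)
  }
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("seq", seq_len(nrow(mat)))
  bad <- setdiff(unique(as.vector(mat)), ALLOWED_CHARS)
  if (length(bad))
    stop_sweepmk("sweepmk_alphabet_error",
                 "illegal alignment character(s): %s", paste(bad, collapse = ", "))
  species <- as.character(species)
  if (length(species) != nrow(mat))
    stop_sweepmk("sweepmk_mapping_error",
                 "species vector length %d does not match %d sequences",
                 length(species), nrow(mat))
  if (!all(species %in% SPECIES_TAGS))
    stop_sweepmk("sweepmk_mapping_error", "unknown species tag(s): %s",
                 paste(setdiff(species, SPECIES_TAGS), collapse = ", "))
  if (frame_offset < 0 || frame_offset >= ncol(mat))
    stop_sweepmk("sweepmk_alignment_error", "frame_offset %d out of range",
                 frame_offset)
  structure(list(
    locus_name = locus_name, chromosome = chromosome,
    samples = rownames(mat), species = species, seq = mat,
    frame_offset = as.integer(frame_offset), segment_id = segment_id
  ), class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("locus_alignment '%s' (%s): %d sequences x %d columns\n",
              x$locus_name, x$chromosome, nrow(x$seq), ncol(x$seq)))
  cat("  species:", paste(sprintf("%s=%d", names(table(x$species)),
                                  table(x$species)), collapse = " "), "\n")
  invisible(x)
}

#' Read an aligned multi-FASTA coding locus
#'
#' @param path Path to an aligned FASTA file.
#' @param species_map Named character vector `sample_id -> species tag`, or a
#'   two-column data frame / TSV file path with columns sample_id, species_tag.
#' @inheritParams locus_alignment
#' @return A `locus_alignment`.
#' @export
read_fasta_alignment <- function(path, species_map, frame_offset = 0L,
                                 locus_name = sub("\\.[^.]*$", "", basename(path)),
                                 chromosome = "other", segment_id = NULL) {
  if (!file.exists(path))
    stop_sweepmk("sweepmk_io_error", "file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (is.character(species_map) && length(species_map) == 1L &&
      file.exists(species_map) && is.null(names(species_map))) {
    tab <- utils::read.table(species_map, header = FALSE, sep = "\t",
                             col.names = c("sample_id", "species_tag"),
                             stringsAsFactors = FALSE)
    species_map <- stats::setNames(tab$species_tag, tab$sample_id)
  } else if (is.data.frame(species_map)) {
    species_map <- stats::setNames(species_map[[2]], species_map[[1]])
  }
  missing_ids <- setdiff(names(seqs), names(species_map))
  if (length(missing_ids))
    stop_sweepmk("sweepmk_mapping_error", "sample id(s) not in species map: %s",
                 paste(missing_ids, collapse = ", "))
  locus_alignment(seqs, unname(species_map[names(seqs)]),
                  locus_name = locus_name, chromosome = chromosome,
                  frame_offset = frame_offset, segment_id = segment_id)
}

## Columns retained under complete deletion, grouped into complete codons.
## A codon is retained only if all three of its columns are free of gaps
## and Ns in every sequence; downstream classification needs the full
## codon context.
retained_codon_columns <- function(aln) {
  L <- ncol(aln$seq)
  n_codons <- (L - aln$frame_offset) %/% 3L
  if (n_codons < 1L) return(integer(0))
  clean_col <- apply(aln$seq, 2, function(col) all(col %in% BASES))
  starts <- aln$frame_offset + 3L * (seq_len(n_codons) - 1L)
  ok <- clean_col[starts + 1L] & clean_col[starts + 2L] & clean_col[starts + 3L]
  starts[ok]
}

#' Classify alignment columns by codon degeneracy
#'
#' Assigns each complete-codon column a fold class (0-fold, 2-fold or
#' 4-fold) by substituting each alternative base into the reference codon
#' and checking amino-acid identity under the standard genetic code.
#' Columns with any gap or N in any sequence are excluded (complete
#' deletion); codons whose reference codon is a stop are excluded with a
#' warning.
#'
#' @param aln A `locus_alignment`.
#' @param reference_rule `"majority-ingroup-codon"` (default; ties broken by
#'   alphabetical codon order) or `"first-sequence"`.
#' @return A `site_classification`: data frame with one row per retained
#'   column (`column` 0-based, `codon_index`, `codon_pos` in 1..3,
#'   `fold_class`, `ref_codon`), with the alignment attached as an attribute.
#' @export
classify_sites <- function(aln,
                           reference_rule = c("majority-ingroup-codon",
                                              "first-sequence")) {
  reference_rule <- match.arg(reference_rule)
  ct <- codon_tables()
  starts <- retained_codon_columns(aln)
  if (!length(starts)) {
    res <- data.frame(column = integer(0), codon_index = integer(0),
                      codon_pos = integer(0), fold_class = character(0),
                      ref_codon = character(0), stringsAsFactors = FALSE)
    return(structure(res, class = c("site_classification", "data.frame"),
                     alignment = aln))
  }
  ingroup_rows <- which(aln$species %in% c("ingroup1", "ingroup2"))
  rows <- vector("list", length(starts))
  dropped_stop <- 0L
  for (k in seq_along(starts)) {
    s <- starts[k]
    cods <- apply(aln$seq[, (s + 1L):(s + 3L), drop = FALSE], 1,
                  paste, collapse = "")
    ref <- if (reference_rule == "first-sequence") cods[1L] else {
      tab <- table(cods[ingroup_rows])
      cands <- names(tab)[tab == max(tab)]
      sort(cands)[1L]  # alphabetical tie-break
    }
    if (ref %in% ct$stops) { dropped_stop <- dropped_stop + 1L; next }
    nsyn <- ct$n_syn_alt[ref, ]
    fold <- ifelse(nsyn == 3L, "4-fold", ifelse(nsyn == 0L, "0-fold", "2-fold"))
    rows[[k]] <- data.frame(
      column = s + 0:2, codon_index = (s - aln$frame_offset) %/% 3L,
      codon_pos = 1:3, fold_class = fold, ref_codon = ref,
      stringsAsFactors = FALSE)
  }
  if (dropped_stop > 0L)
    warning(sprintf("%d codon(s) with internal stop reference codon excluded",
                    dropped_stop))
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(column = integer(0), codon_index = integer(0),
                      codon_pos = integer(0), fold_class = character(0),
                      ref_codon = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("site_classification", "data.frame"),
            alignment = aln)
}

## Synonymous/nonsynonymous status of a difference between two bases at
## codon position pos (1..3) of codon context `ctx` (the other two
## positions are taken from ctx).
substitution_class <- function(ctx, pos, base_a, base_b) {
  ct <- codon_tables()
  cs <- strsplit(ctx, "")[[1]]
  a <- cs; a[pos] <- base_a
  b <- cs; b[pos] <- base_b
  if (ct$aa[[paste(a, collapse = "")]] == ct$aa[[paste(b, collapse = "")]])
    "synonymous" else "nonsynonymous"
}

#' Count potential synonymous and nonsynonymous sites (Nei-Gojobori)
#'
#' Each retained codon contributes, per position, the fraction of one-step
#' changes that are synonymous (0, 1/3, 2/3 or 1); per codon the
#' synonymous and nonsynonymous potentials sum to exactly 3. Counts are
#' averaged over the selected sequences.
#'
#' @param aln A `locus_alignment`.
#' @param species Optional species tag (or vector of tags) restricting the
#'   sequences averaged over; default all sequences.
#' @param classification Optional precomputed `classify_sites` result.
#' @return List with `L_syn`, `L_nonsyn` and `n_codons` (retained codons).
#' @export
count_potential_sites <- function(aln, species = NULL, classification = NULL) {
  ct <- codon_tables()
  cls <- classification %||% classify_sites(aln)
  starts <- unique(cls$column[cls$codon_pos == 1L])
  if (!length(starts))
    stop_sweepmk("sweepmk_empty_data_error", "no retained complete codons")
  rows <- if (is.null(species)) seq_len(nrow(aln$seq)) else
    which(aln$species %in% species)
  if (!length(rows))
    stop_sweepmk("sweepmk_mapping_error", "no sequences for species %s",
                 paste(species, collapse = ","))
  per_seq_syn <- vapply(rows, function(r) {
    cods <- vapply(starts, function(s)
      paste(aln$seq[r, (s + 1L):(s + 3L)], collapse = ""), character(1))
    sum(ct$syn_frac[cods, , drop = FALSE])
  }, numeric(1))
  L_total <- 3 * length(starts)
  L_syn <- mean(per_seq_syn)
  list(L_syn = L_syn, L_nonsyn = L_total - L_syn, n_codons = length(starts))
}
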