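test_that("FASTA reading validates length, alphabet and species mapping", {
  map <- c(a = "ingroup1", b = "ingroup1", c = "ingroup2", d = "ingroup2",
           o = "outgroup")
  path <- write_tmp_fasta(list(a = "ATGGGAGGG", b = "ATGGGAGGG",
                               c = "ATGGGAGGG", d = "ATGGGAGGG",
                               o = "ATGGGAGGG"))
  aln <- read_fasta_alignment(path, map)
  expect_s3_class(aln, "locus_alignment")
  expect_identical(ncol(aln$seq), 9L)
  expect_identical(aln$samples, c("a", "b", "c", "d", "o"))  # order kept
  expect_identical(nrow(classify_sites(aln)), 9L)            # 3 codons

  bad <- write_tmp_fasta(list(a = "ATGGGAGGR", b = "ATGGGAGGG",
                              c = "ATGGGAGGG", d = "ATGGGAGGG",
                              o = "ATGGGAGGG"))
  expect_error(read_fasta_alignment(bad, map), class = "sweepmk_alphabet_error")

  ragged <- write_tmp_fasta(list(a = "ATGGGAGGG", b = "ATGGGAGGGATG",
                                 c = "ATGGGAGGG", d = "ATGGGAGGG",
                                 o = "ATGGGAGGG"))
  expect_error(read_fasta_alignment(ragged, map),
               class = "sweepmk_alignment_error")

  unmapped <- write_tmp_fasta(list(zz = "ATGGGAGGG", b = "ATGGGAGGG",
                                   c = "ATGGGAGGG", d = "ATGGGAGGG",
                                   o = "ATGGGAGGG"))
  expect_error(read_fasta_alignment(unmapped, map),
               class = "sweepmk_mapping_error")
})

test_that("degeneracy classes match the standard genetic code", {
  sp <- c("ingroup1", "ingroup1", "ingroup2", "ingroup2", "outgroup")
  aln <- aln_from_codons(c("GGG", "ATG", "ATT"), c("GGG", "ATG", "ATT"),
                         c("GGG", "ATG", "ATT"), c("GGG", "ATG", "ATT"),
                         c("GGG", "ATG", "ATT"), species = sp)
  cls <- classify_sites(aln)
  # GGG: third position fourfold (glycine whatever the base)
  expect_identical(cls$fold_class[cls$ref_codon == "GGG"],
                   c("0-fold", "0-fold", "4-fold"))
  # ATG: every change is nonsynonymous
  expect_identical(cls$fold_class[cls$ref_codon == "ATG"], rep("0-fold", 3))
  # ATT third position: ATC/ATA synonymous, ATG not -> neither 0- nor 4-fold
  expect_identical(cls$fold_class[cls$ref_codon == "ATT"],
                   c("0-fold", "0-fold", "2-fold"))
})

test_that("majority reference rule is order-invariant with alphabetical ties", {
  sp4 <- c("ingroup1", "ingroup1", "ingroup2", "ingroup2")
  a <- aln_from_codons(c("GGA"), c("GGA"), c("GGG"), c("GGG"), species = sp4)
  b <- aln_from_codons(c("GGG"), c("GGG"), c("GGA"), c("GGA"), species = sp4)
  # 2-2 tie -> alphabetical: GGA in both orders
  expect_identical(classify_sites(a)$ref_codon[1], "GGA")
  expect_identical(classify_sites(b)$ref_codon[1], "GGA")
})

test_that("complete deletion excludes gapped columns and stop-codon references", {
  sp <- c("ingroup1", "ingroup1", "ingroup2", "ingroup2")
  aln <- aln_from_codons(c("GGG", "AAA"), c("GGG", "AAA"),
                         c("GG-", "AAA"), c("GGG", "AAA"), species = sp)
  cls <- classify_sites(aln)
  expect_identical(unique(cls$codon_index), 1L)  # gapped codon dropped whole
  # a sequence of all gaps removes every column
  allgap <- locus_alignment(
    c(s1 = "GGGAAA", s2 = "GGGAAA", s3 = "GGGAAA", s4 = "------"),
    c("ingroup1", "ingroup1", "ingroup2", "ingroup2"))
  expect_identical(nrow(classify_sites(allgap)), 0L)
  # internal stop in the reference codon: warned and excluded
  stopaln <- aln_from_codons(c("TAA", "GGG"), c("TAA", "GGG"),
                             c("TAA", "GGG"), c("TAA", "GGG"), species = sp)
  expect_warning(cls2 <- classify_sites(stopaln), "stop")
  expect_identical(unique(cls2$ref_codon), "GGG")
})

test_that("Nei-Gojobori potential site counts sum to 3 per codon", {
  sp <- c("ingroup1", "ingroup1", "ingroup2", "ingroup2")
  gly <- aln_from_codons(c("GGG"), c("GGG"), c("GGG"), c("GGG"), species = sp)
  pot <- count_potential_sites(gly)
  expect_equal(pot$L_syn, 1.0)    # 3 synonymous one-step changes, all 3rd pos
  expect_equal(pot$L_nonsyn, 2.0)
  met <- aln_from_codons(c("ATG"), c("ATG"), c("ATG"), c("ATG"), species = sp)
  expect_equal(count_potential_sites(met)$L_syn, 0.0)
  expect_equal(count_potential_sites(met)$L_nonsyn, 3.0)
  # averaging identical sequences changes nothing; totals always sum to 3/codon
  mixed <- aln_from_codons(c("GGG", "ATT", "CGA"), c("GGG", "ATT", "CGA"),
                           c("GGG", "ATT", "CGA"), c("GGG", "ATT", "CGA"),
                           species = sp)
  pm <- count_potential_sites(mixed)
  expect_equal(pm$L_syn + pm$L_nonsyn, 9.0)
  ct <- sweepmk:::codon_tables()
  expect_true(all(ct$syn_frac %in% c(0, 1/3, 2/3, 1)))
})
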