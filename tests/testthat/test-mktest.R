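test_that("MK tables are built by the pooled-polymorphism rules", {
  sp <- c(rep("ingroup1", 3), rep("ingroup2", 3), "outgroup")
  # fixed GGG vs GGA at a fourfold site -> one synonymous divergence
  fix <- aln_from_codons(c("GGG"), c("GGG"), c("GGG"),
                         c("GGA"), c("GGA"), c("GGA"), c("GGG"), species = sp)
  t1 <- build_mk_table(fix)
  expect_identical(c(t1$syn_poly, t1$syn_div, t1$nonsyn_poly, t1$nonsyn_div),
                   c(0L, 1L, 0L, 0L))
  # ATG/ATA segregating in ingroup1 -> one nonsynonymous polymorphism (M->I)
  poly <- aln_from_codons(c("ATG"), c("ATA"), c("ATG"),
                          c("ATG"), c("ATG"), c("ATG"), c("ATG"), species = sp)
  t2 <- build_mk_table(poly)
  expect_identical(c(t2$syn_poly, t2$syn_div, t2$nonsyn_poly, t2$nonsyn_div),
                   c(0L, 0L, 1L, 0L))
  # polymorphic in ingroup1 while ingroup2 is fixed for another state:
  # counted once, as polymorphism
  both <- aln_from_codons(c("GGG"), c("GGA"), c("GGG"),
                          c("GGA"), c("GGA"), c("GGA"), c("GGG"), species = sp)
  t3 <- build_mk_table(both)
  expect_identical(c(t3$syn_poly, t3$syn_div, t3$nonsyn_poly, t3$nonsyn_div),
                   c(1L, 0L, 0L, 0L))
  expect_error(build_mk_table(aln_from_codons(c("GGG"), c("GGG"),
                                              species = rep("ingroup1", 2))),
               class = "sweepmk_config_error")
})

test_that("MK test methods, neutrality index and alpha are consistent", {
  tab <- mk_table(30, 20, 10, 40)
  for (m in c("chi2", "g", "fisher")) {
    res <- mk_test(tab, method = m)
    expect_gte(res$p_value, 0); expect_lte(res$p_value, 1)
    expect_equal(res$alpha_mk, 1 - res$neutrality_index)
    expect_equal(res$neutrality_index, (10 / 30) / (40 / 20))
  }
  # perfectly proportional table: chi2 statistic exactly 0, p = 1
  flat <- mk_test(mk_table(10, 10, 10, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # zero margin is undefined, like a divergence-free gene
  expect_error(mk_test(mk_table(24, 44, 0, 0)),
               class = "sweepmk_undefined_test_error")
})

test_that("Fisher variant equals exhaustive enumeration over fixed margins", {
  cases <- list(c(5, 3, 2, 8), c(12, 7, 9, 4), c(1, 9, 10, 2), c(6, 6, 6, 7))
  for (cc in cases) {
    got <- mk_test(mk_table(cc[1], cc[2], cc[3], cc[4]), method = "fisher")
    expect_equal(got$p_value, fisher_oracle(cc[1], cc[2], cc[3], cc[4]),
                 tolerance = 1e-9)
  }
})

test_that("MK construction is invariant to swapping the ingroup labels", {
  aln <- generate_mk_alignment(mk_table(7, 4, 5, 9), n1 = 5, n2 = 4,
                               codons = 80, seed = 21)
  swapped <- aln
  swapped$species <- ifelse(aln$species == "ingroup1", "ingroup2",
                            ifelse(aln$species == "ingroup2", "ingroup1",
                                   aln$species))
  a <- build_mk_table(aln); b <- build_mk_table(swapped)
  expect_identical(unclass(a)[1:4], unclass(b)[1:4])
})

test_that("Nei-Gojobori dN/dS with Jukes-Cantor correction", {
  sp <- c("ingroup1", "ingroup2", "outgroup")
  same <- aln_from_codons(rep("GGG", 100), rep("GGG", 100), rep("GGG", 100),
                          species = sp)
  r0 <- pairwise_dnds(same)
  expect_equal(r0$dN, 0); expect_equal(r0$dS, 0)
  # one GGG->GGA difference over 100 codons
  c2 <- rep("GGG", 100); c2[50] <- "GGA"
  one <- aln_from_codons(rep("GGG", 100), c2, rep("GGG", 100), species = sp)
  r1 <- pairwise_dnds(one)
  expect_equal(r1$S_d, 1)
  expect_equal(r1$dS, -0.75 * log(1 - 4 * (1 / r1$L_syn) / 3))
  expect_equal(r1$dN, 0)
  # every fourfold site differing: p_S = 1 >= 3/4 saturates
  sat <- aln_from_codons(rep("GGG", 30), rep("GGA", 30), rep("GGG", 30),
                         species = sp)
  expect_error(pairwise_dnds(sat), class = "sweepmk_saturation_error")
})

test_that("codon-pair pathway counting averages minimal paths", {
  # TTT -> GTA: paths TTT->GTT->GTA (non, syn... enumerate by hand)
  d <- sweepmk:::ng_codon_diffs("TTT", "GTA")
  expect_equal(unname(d["syn"] + d["nonsyn"]), 2)
  # single-step difference is unambiguous
  d1 <- sweepmk:::ng_codon_diffs("GGG", "GGA")
  expect_equal(unname(d1["syn"]), 1)
  expect_equal(unname(d1["nonsyn"]), 0)
})
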