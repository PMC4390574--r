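test_that("BH adjustment matches the step-up closed form and oracle", {
  out <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$adjusted, rep(0.04, 4))
  expect_equal(bh_adjust(0.37)$adjusted, 0.37)
  set.seed(2)
  for (rep in 1:200) {
    p <- runif(sample(1:40, 1))
    got <- bh_adjust(p)$adjusted
    expect_equal(got, bh_oracle(p), tolerance = 1e-12)
    # monotone in the raw ranks
    expect_true(all(diff(got[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(numeric(0)), class = "sweepmk_config_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "sweepmk_config_error")
})

test_that("grouped correction uses the four families and stays local", {
  pset <- expand.grid(gene_region = c("a", "b", "c"),
                      species = c("ingroup1", "ingroup2"),
                      test = c("sweed", "mk", "omega"),
                      stringsAsFactors = FALSE)
  pset$demographic_scenario <- "constant"
  set.seed(6)
  pset$p_raw <- round(runif(nrow(pset)), 3)
  adj <- group_and_adjust(pset)
  for (fam in unique(adj$family)) {
    idx <- adj$family == fam
    expect_equal(adj$p_adj[idx], bh_oracle(adj$p_raw[idx]), tolerance = 1e-12)
  }
  # sweed and mk share a family per species; omega corrected apart
  expect_setequal(unique(adj$family[adj$test %in% c("sweed", "mk")]),
                  c("sfs|ingroup1", "sfs|ingroup2"))
  expect_setequal(unique(adj$family[adj$test == "omega"]),
                  c("omega|ingroup1", "omega|ingroup2"))
  # moving a record between families only perturbs the two families touched
  mv <- which(pset$test == "omega" & pset$species == "ingroup1")[1]
  moved <- pset; moved$test[mv] <- "sweed"
  adj2 <- group_and_adjust(moved)
  still <- adj$family == "omega|ingroup2"
  expect_equal(adj2$p_adj[still], adj$p_adj[still], tolerance = 1e-12)
  rest <- which(adj2$family == "omega|ingroup1")
  expect_equal(adj2$p_adj[rest], bh_oracle(pset$p_raw[rest]),
               tolerance = 1e-12)
  expect_error(group_and_adjust(transform(pset, test = "paml")),
               class = "sweepmk_classification_error")
})

test_that("identical p-values stay unchanged within a family", {
  pset <- data.frame(gene_region = letters[1:10], species = "ingroup1",
                     test = "sweed", demographic_scenario = "constant",
                     p_raw = rep(0.05, 10))
  expect_equal(group_and_adjust(pset)$p_adj, rep(0.05, 10))
})

test_that("bootstrap overlap hits its degenerate limits", {
  uni <- generate_outlier_universe(30, genome_bp = 1e5,
                                   n_outlier_intervals = 0, seed = 3)
  study <- uni$loci[1:6, ]
  # no outliers: observed 0, every draw 0, ties count as >=
  r0 <- bootstrap_overlap(study, uni$outliers, uni$loci, n_draws = 50, seed = 1)
  expect_identical(r0$observed, 0L)
  expect_equal(r0$p_value, 1)
  # outliers covering each whole chromosome: all loci always hit
  full <- data.frame(chrom = c("X", "2", "3"), start = 0, end = 1e5)
  r1 <- bootstrap_overlap(study, full, uni$loci, n_draws = 50, seed = 1)
  expect_identical(r1$observed, nrow(study))
  expect_equal(r1$p_value, 1)
  expect_error(bootstrap_overlap(study, full, uni$loci[1, ], n_draws = 10),
               class = "sweepmk_sampling_error")
})

test_that("the distance rule is a closed threshold on boundary distance", {
  outl <- data.frame(chrom = "X", start = 1000, end = 2000)
  at <- data.frame(chrom = "X", start = 2500, end = 3000)     # distance 500
  inside <- data.frame(chrom = "X", start = 1500, end = 1600) # overlap
  beyond <- data.frame(chrom = "X", start = 2501, end = 3000) # distance 501
  expect_identical(sweepmk:::count_near_outliers(at, outl, 500), 1L)
  expect_identical(sweepmk:::count_near_outliers(beyond, outl, 500), 0L)
  expect_identical(sweepmk:::count_near_outliers(inside, outl, 0), 1L)
})

test_that("bootstrap p converges to exhaustive enumeration on a toy universe", {
  universe <- data.frame(
    name = paste0("u", 1:5),
    chrom = c("X", "X", "X", "2", "2"),
    start = c(100, 5000, 9000, 100, 9000),
    end = c(200, 5100, 9100, 200, 9100))
  outliers <- data.frame(chrom = c("X", "2"), start = c(0, 0),
                         end = c(300, 300))
  study <- universe[c(1, 2, 4), ]   # 2 on X, 1 on chromosome 2
  observed <- sweepmk:::count_near_outliers(study, outliers, 0)
  # enumerate all chromosome-matched subsets: choose 2 of 3 X, 1 of 2 on 2
  counts <- c()
  for (xx in list(c(1, 2), c(1, 3), c(2, 3))) for (aa in c(4, 5)) {
    counts <- c(counts,
                sweepmk:::count_near_outliers(universe[c(xx, aa), ],
                                              outliers, 0))
  }
  exact <- mean(counts >= observed)
  got <- bootstrap_overlap(study, outliers, universe, n_draws = 3000,
                           seed = 8)
  expect_identical(got$observed, observed)
  expect_equal(got$p_value, exact, tolerance = 0.03)
})
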