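test_that("simulator means match Watterson and pairwise expectations", {
  n <- 10; theta <- 10; reps <- 300
  S <- numeric(reps); pi <- numeric(reps)
  for (i in seq_len(reps)) {
    s <- summarize_haplotypes(simulate_coalescent(n, theta, seed = i))
    S[i] <- s$S; pi[i] <- s$pi
  }
  a_n <- sum(1 / (1:(n - 1)))   # harmonic sum computed here, not imported
  expect_lt(abs(mean(S) - theta * a_n), 3 * sd(S) / sqrt(reps))
  expect_lt(abs(mean(pi) - theta), 3 * sd(pi) / sqrt(reps))
})

test_that("degenerate demographies reproduce the constant model exactly", {
  for (seed in c(3, 17, 91)) {
    base <- simulate_coalescent(6, 5, seed = seed)
    g0 <- simulate_coalescent(6, 5, seed = seed,
                              dem = demography("exponential_growth", rate = 0))
    bn <- simulate_coalescent(6, 5, seed = seed,
                              dem = demography("bottleneck_3epoch",
                                               n_mid = 1, n_anc = 1,
                                               t1 = 0.1, t2 = 0.5))
    expect_identical(base$mat, g0$mat)
    expect_identical(base$positions, bn$positions)
  }
})

test_that("unfolded SFS under neutrality is proportional to 1/i", {
  n <- 6; reps <- 600
  dac <- unlist(lapply(seq_len(reps), function(i)
    colSums(simulate_coalescent(n, 5, seed = 5000 + i)$mat)))
  obs <- tabulate(dac, nbins = n - 1)
  expected <- (1 / (1:(n - 1))) / sum(1 / (1:(n - 1)))
  gof <- suppressWarnings(chisq.test(obs, p = expected))
  expect_gt(gof$p.value, 1e-3)
})

test_that("recombination keeps marginal expectations, reduces S variance", {
  reps <- 250; n <- 8; theta <- 8
  S0 <- vapply(seq_len(reps), function(i)
    ncol(simulate_coalescent(n, theta, seed = 100 + i)$mat), numeric(1))
  Sr <- vapply(seq_len(reps), function(i)
    ncol(simulate_coalescent(n, theta, rho_locus = 20, seed = 100 + i)$mat),
    numeric(1))
  a_n <- sum(1 / (1:(n - 1)))
  expect_lt(abs(mean(Sr) - theta * a_n), 3 * sd(Sr) / sqrt(reps))
  # independent marginal trees average out: strictly smaller spread
  expect_lt(var(Sr), var(S0))
  # every column segregating, positions sorted
  hm <- simulate_coalescent(n, theta, rho_locus = 10, seed = 77)
  expect_true(all(colSums(hm$mat) %in% 1:(n - 1)))
  expect_false(is.unsorted(hm$positions))
})

test_that("prior draws respect ranges, degeneracy and the seed contract", {
  spec <- list(theta_per_site = c(0.006, 0.009), t1 = c(0.05, 0.05))
  d1 <- draw_priors(spec, 500, seed = 2)
  expect_gte(min(d1$theta_per_site), 0.006)
  expect_lte(max(d1$theta_per_site), 0.009)
  expect_true(all(d1$t1 == 0.05))
  expect_identical(draw_priors(spec, 500, seed = 2), d1)
  expect_false(identical(draw_priors(spec, 500, seed = 3)$theta_per_site,
                         d1$theta_per_site))
  expect_error(draw_priors(list(theta_per_site = c(2, 1)), 10),
               class = "sweepmk_config_error")
})

test_that("null distributions are deterministic and feed empirical p-values", {
  spec <- list(theta_per_site = c(0.005, 0.01))
  nd1 <- null_distribution("max_CLR", spec, "constant", n = 6,
                           locus_length = 1000, n_sims = 100, seed = 4)
  nd2 <- null_distribution("max_CLR", spec, "constant", n = 6,
                           locus_length = 1000, n_sims = 100, seed = 4)
  expect_identical(nd1$values, nd2$values)
  expect_false(is.unsorted(nd1$values))
  expect_equal(empirical_pvalue(max(nd1$values) + 1, nd1), 1 / 101)
  expect_equal(empirical_pvalue(-1, nd1), 1)
})

test_that("ms-format round trip preserves replicates byte for byte", {
  reps <- lapply(1:3, function(i) simulate_coalescent(5, 4, seed = i))
  p1 <- tempfile(); p2 <- tempfile()
  write_ms(reps, p1)
  back <- read_ms(p1, locus_length_bp = 1000L)
  expect_equal(length(back), 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$mat, reps[[i]]$mat)
    expect_equal(back[[i]]$positions, reps[[i]]$positions, tolerance = 1e-6)
  }
  write_ms(back, p2)
  expect_identical(readLines(p1)[-1], readLines(p2)[-1])
})

test_that("demography construction rejects invalid parameters", {
  expect_error(demography("bottleneck_3epoch", t1 = 0.3, t2 = 0.1),
               class = "sweepmk_config_error")
  expect_error(demography("bottleneck_3epoch", n_mid = 0),
               class = "sweepmk_config_error")
  expect_error(demography("exponential_growth", rate = -1),
               class = "sweepmk_config_error")
  expect_error(simulate_coalescent(1, 5), class = "sweepmk_config_error")
})
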