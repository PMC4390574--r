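test_that("expected SFS has the neutral 1/i limit and deleterious skew", {
  for (n in c(6, 9)) {
    e0 <- expected_sfs(0, n)
    expect_equal(e0, 1 / seq_len(n - 1), tolerance = 1e-8)
  }
  em <- expected_sfs(-100, 9)
  expect_gt(em[1] / sum(em), 0.9)   # strong selection: nearly all singletons
  for (g in c(-500, -50, -1, 0, 1, 50)) {
    v <- expected_sfs(g, 9)
    expect_true(all(is.finite(v) & v > 0))
  }
})

test_that("fixation rate is stable from nearly neutral to lethal", {
  u <- sweepmk:::fixation_rate(c(0, -1e-8, -1, -100, -1000, 1))
  expect_equal(u[1], 1)
  expect_equal(u[2], 1, tolerance = 1e-6)
  expect_true(all(diff(u[1:5]) <= 0))      # more deleterious fixes less
  expect_true(all(is.finite(u)))
})

test_that("simulated data are seeded and respect the generative alpha", {
  d1 <- simulate_dfe_data(0.4, 800, 0.8, 0.01, 4000, 12000, 9, seed = 5)
  d2 <- simulate_dfe_data(0.4, 800, 0.8, 0.01, 4000, 12000, 9, seed = 5)
  expect_identical(d1$neutral_sfs$counts, d2$neutral_sfs$counts)
  expect_identical(d1$D_n, d2$D_n)
  # alpha_true = 0 leaves only deleterious + neutral divergence
  tr <- attr(simulate_dfe_data(0.4, 800, 0, 0.01, 4000, 12000, 9, seed = 6),
             "truth")
  expect_equal(tr$alpha_true, 0)
  expect_error(simulate_dfe_data(0.4, 800, 1, 0.01, 4000, 12000, 9),
               class = "sweepmk_config_error")
})

test_that("the fit is deterministic and alpha obeys its identity per draw", {
  grid <- sweepmk:::dfe_grid(6)
  dat <- simulate_dfe_data(0.4, 500, 0.7, 0.01, 3000, 9000, 6,
                           t_div = 10, seed = 11)
  f1 <- suppressWarnings(fit_dfe(dat, n_iter = 400, burn_in = 200,
                                 seed = 12, grid = grid))
  f2 <- suppressWarnings(fit_dfe(dat, n_iter = 400, burn_in = 200,
                                 seed = 12, grid = grid))
  expect_identical(f1$chain, f2$chain)
  expect_identical(f1$alpha, f2$alpha)
  # recompute alpha from a few raw draws: must match exactly
  for (k in c(1, 100, 400)) {
    pp <- f1$chain[k, ]
    w <- sweepmk:::dfe_weights(grid, exp(pp[2]), exp(pp[3]))
    a <- 1 - dat$D_s * (dat$L_nonsyn / dat$L_syn) * sum(w * grid$u) / dat$D_n
    expect_equal(f1$alpha_draws[k], a, tolerance = 1e-12)
  }
  # the credibility interval brackets the point estimate
  expect_gte(f1$alpha, f1$alpha_ci[1])
  expect_lte(f1$alpha, f1$alpha_ci[2])
})

test_that("theta recovers within 10% on neutral data with fixed distortions", {
  grid <- sweepmk:::dfe_grid(9)
  # nearly neutral DFE so both classes behave neutrally; generous L
  dat <- simulate_dfe_data(beta = 2, gmean = 1e-3, alpha_true = 0,
                           theta_s = 0.01, L_syn = 50000, L_nonsyn = 50000,
                           n = 9, t_div = 5, seed = 31)
  fit <- suppressWarnings(fit_dfe(dat, n_iter = 800, burn_in = 300,
                                  seed = 32, fix_r = TRUE, grid = grid))
  expect_lt(abs(fit$theta_s - 0.01) / 0.01, 0.10)
  expect_lt(abs(fit$alpha), 0.15)   # no adaptive divergence to find
})

test_that("pooling loci into a DFE input sums classes and filters chromosomes", {
  a1 <- generate_mk_alignment(mk_table(4, 6, 2, 8), n1 = 9, n2 = 6,
                              codons = 200, seed = 81)
  a1$chromosome <- "X"
  a2 <- generate_mk_alignment(mk_table(3, 5, 1, 7), n1 = 9, n2 = 6,
                              codons = 200, seed = 82)
  a2$chromosome <- "2"
  inp <- dfe_input_from_alignments(list(a1, a2), "ingroup1", m = 9, seed = 3)
  expect_s3_class(inp, "dfe_input")
  expect_identical(inp$D_s, 11L)   # synonymous divergences summed
  expect_identical(inp$D_n, 15L)
  expect_true(all(inp$neutral_sfs$counts == round(inp$neutral_sfs$counts)))
  x_only <- dfe_input_from_alignments(list(a1, a2), "ingroup1", m = 9,
                                      chromosomes = "X", seed = 3)
  expect_identical(x_only$D_s, 6L)
  expect_error(dfe_input_from_alignments(list(a1), "ingroup1", m = 9,
                                         chromosomes = "3"),
               class = "sweepmk_config_error")
})
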