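## Gamma-DFE estimation of the adaptive proportion alpha from neutral
## (4-fold) and selected (0-fold) site frequency spectra plus divergence
## counts, with frequency-class distortion parameters r_i absorbing
## demography, sampled by random-walk Metropolis.

## Diffusion sojourn density of a deleterious mutation with scaled
## selection gamma (< 0), written in an overflow-safe form. gamma = 0 gives
## the neutral 1/q.
sojourn_density <- function(q, gamma) {
  if (gamma == 0) return(1 / q)
  if (gamma < 0) {
    g <- -gamma
    (exp(-g * q) - exp(-g)) / ((1 - exp(-g)) * q * (1 - q))
  } else {
    (1 - exp(-gamma * (1 - q))) / ((1 - exp(-gamma)) * q * (1 - q))
  }
}

#' Expected SFS under a fixed scaled selection coefficient
#'
#' `E[i | gamma] = integral binom(n, i) q^i (1-q)^(n-i) tau(q; gamma) dq`
#' over `q` in (0,1), where `tau` is the sojourn density. The neutral
#' limit (`gamma = 0`) is `1/i`.
#'
#' @param gamma Scaled selection coefficient (negative = deleterious).
#' @param n Sample size (`>= 2`).
#' @param rel_tol Quadrature relative tolerance.
#' @return Vector of unnormalized expectations over `i = 1..n-1`.
#' @export
expected_sfs <- function(gamma, n, rel_tol = 1e-9) {
  if (n < 2L) stop_sweepmk("sweepmk_config_error", "n must be >= 2")
  vapply(seq_len(n - 1L), function(i) {
    f <- function(q) exp(lchoose(n, i) + i * log(q) + (n - i) * log1p(-q)) *
      sojourn_density(q, gamma)
    ## for strongly deleterious gamma the mass sits near q ~ i/|gamma|;
    ## split there so the quadrature resolves the boundary layer
    cuts <- if (gamma < -50) {
      cut <- min(0.5, (i + 30) / abs(gamma))
      c(0, cut, 1)
    } else c(0, 1)
    val <- 0
    for (s in seq_len(length(cuts) - 1L)) {
      out <- tryCatch(
        stats::integrate(f, cuts[s], cuts[s + 1L], rel.tol = rel_tol,
                         subdivisions = 400L),
        error = function(e) NULL)
      if (is.null(out) || out$message != "OK")
        stop_sweepmk("sweepmk_numerical_error",
                     "quadrature failed for gamma=%g, i=%d", gamma, i)
      val <- val + out$value
    }
    val
  }, numeric(1))
}

## Relative fixation probability of a mutation with scaled selection gamma,
## u(gamma) = gamma / (1 - exp(-gamma)); overflow-safe for gamma << 0.
fixation_rate <- function(gamma) {
  out <- numeric(length(gamma))
  neg <- gamma < 0; pos <- gamma > 0
  out[gamma == 0] <- 1
  g <- -gamma[neg]
  out[neg] <- ifelse(g > 700, 0, g / expm1(pmin(g, 700)))
  out[pos] <- gamma[pos] / (-expm1(-gamma[pos]))
  out
}

#' Inputs for the DFE/alpha fit
#' @param neutral_sfs,selected_sfs `sfs` objects at a common sample size
#'   (4-fold neutral class, 0-fold selected class).
#' @param D_s,D_n Neutral and selected fixed-difference counts.
#' @param L_syn,L_nonsyn Potential site totals for the two classes.
#' @return A `dfe_input`.
#' @export
dfe_input <- function(neutral_sfs, selected_sfs, D_s, D_n, L_syn, L_nonsyn) {
  if (neutral_sfs$n != selected_sfs$n)
    stop_sweepmk("sweepmk_config_error",
                 "neutral and selected SFS sample sizes differ")
  if (any(c(D_s, D_n) < 0) || any(c(L_syn, L_nonsyn) <= 0))
    stop_sweepmk("sweepmk_config_error", "invalid divergence/site counts")
  structure(list(neutral_sfs = neutral_sfs, selected_sfs = selected_sfs,
                 D_s = D_s, D_n = D_n, L_syn = L_syn, L_nonsyn = L_nonsyn,
                 n = neutral_sfs$n), class = "dfe_input")
}

#' Pool per-locus spectra into a DFE input
#'
#' Sums the 4-fold (neutral) and 0-fold (selected) spectra, divergence
#' counts and site totals across loci, after projecting every locus to a
#' common sample size. `chromosomes` restricts the pool (e.g. `"X"` or
#' `c("2", "3")`) so X-linked and autosomal loci can be fitted separately.
#'
#' @param alignments List of `locus_alignment` objects (each with both
#'   ingroups and the outgroup).
#' @param species Ingroup species tag whose spectra are used.
#' @param m Common projected sample size (e.g. 9 or 6).
#' @param chromosomes Optional chromosome filter.
#' @param seed Seed for the random-subsample projection; the fit needs
#'   integer counts, so each locus is downsampled by one seeded
#'   hypergeometric realization (the literal random selection of `m`
#'   alleles), not by the expectation.
#' @return A `dfe_input`.
#' @export
dfe_input_from_alignments <- function(alignments, species, m,
                                      chromosomes = NULL, seed = 1L) {
  if (!is.null(chromosomes))
    alignments <- Filter(function(a) a$chromosome %in% chromosomes,
                         alignments)
  if (!length(alignments))
    stop_sweepmk("sweepmk_config_error", "no loci left after filtering")
  neu <- numeric(m - 1L); sel <- numeric(m - 1L)
  D_s <- 0L; D_n <- 0L; Ls <- 0; Ln <- 0
  for (k in seq_along(alignments)) {
    aln <- alignments[[k]]
    cls <- classify_sites(aln)
    s4 <- compute_sfs(aln, species, "4-fold", classification = cls)
    s0 <- compute_sfs(aln, species, "0-fold", classification = cls)
    neu <- neu + project_sfs(s4, m, mode = "sample",
                             seed = derive_seed(seed, 2L * k))$counts
    sel <- sel + project_sfs(s0, m, mode = "sample",
                             seed = derive_seed(seed, 2L * k + 1L))$counts
    tab <- build_mk_table(aln, classification = cls)
    D_s <- D_s + tab$syn_div; D_n <- D_n + tab$nonsyn_div
    pot <- count_potential_sites(aln, species = species,
                                 classification = cls)
    Ls <- Ls + pot$L_syn; Ln <- Ln + pot$L_nonsyn
  }
  dfe_input(new_sfs(neu, m, "4-fold"), new_sfs(sel, m, "0-fold"),
            D_s, D_n, Ls, Ln)
}

## Fixed quadrature grid over deleterious effect magnitudes g = -gamma,
## log-spaced; returns nodes, log-step, and the per-node expected SFS
## matrix and fixation rates for sample size n.
dfe_grid <- function(n, n_nodes = 48L, g_min = 1e-3, g_max = 1e4) {
  lg <- seq(log(g_min), log(g_max), length.out = n_nodes)
  g <- exp(lg)
  E <- vapply(g, function(gl) expected_sfs(-gl, n, rel_tol = 1e-8),
              numeric(n - 1L))
  list(g = g, dlog = lg[2] - lg[1], E = E, u = fixation_rate(-g))
}

## Gamma-DFE quadrature weights for shape beta and mean gmean of g.
dfe_weights <- function(grid, beta, gmean) {
  w <- stats::dgamma(grid$g, shape = beta, rate = beta / gmean) *
    grid$g * grid$dlog
  s <- sum(w)
  if (s <= 0) return(NULL)
  w / s
}

#' Fit the gamma DFE and estimate alpha
#'
#' Poisson likelihood over SFS bins: neutral class
#' `E_i = theta_s L_syn r_i / i`, selected class
#' `E_i = theta_s L_nonsyn r_i * int E[i|gamma] f(gamma; beta, mean) dgamma`,
#' with `r_1 = 1` for identifiability and uniform priors within `bounds`.
#' Sampled by seeded random-walk Metropolis (componentwise, log scale).
#' Each posterior draw implies
#' `alpha = 1 - D_s (L_nonsyn/L_syn) int u(gamma) f(gamma) dgamma / D_n`;
#' the credibility interval is the posterior 2.5/97.5 percentile range.
#'
#' @param input A `dfe_input`.
#' @param n_iter Post-burn-in sweeps kept (default 1500).
#' @param burn_in Burn-in sweeps (default 500).
#' @param seed Integer seed.
#' @param fix_r Fix all distortion parameters at 1 (no demography terms).
#' @param bounds Named list of uniform prior bounds (`beta`, `gmean`,
#'   `theta_s`, `r`).
#' @param grid Optional precomputed [dfe_grid()] (reused across fits).
#' @param step Proposal scale on the log scale.
#' @return A `dfe_fit`: `alpha` (posterior median), `alpha_ci`,
#'   posterior means of `beta`, `gmean`, `theta_s`, `r`, chains and
#'   diagnostics (acceptance rate, split R-hat for alpha).
#' @export
fit_dfe <- function(input, n_iter = 1500L, burn_in = 500L, seed = 1L,
                    fix_r = FALSE,
                    bounds = list(beta = c(0.01, 5), gmean = c(1e-3, 1e4),
                                  theta_s = c(1e-8, 1), r = c(0.01, 100)),
                    grid = NULL, step = 0.25) {
  n <- input$n
  grid <- grid %||% dfe_grid(n)
  neu <- input$neutral_sfs$counts
  sel <- input$selected_sfs$counts
  ii <- seq_len(n - 1L)
  n_r <- if (fix_r) 0L else n - 2L  # r_2..r_{n-1}
  ## parameter vector on log scale: theta_s, beta, gmean, r_2..r_{n-1}
  loglik <- function(p) {
    theta_s <- exp(p[1]); beta <- exp(p[2]); gmean <- exp(p[3])
    r <- c(1, if (n_r) exp(p[4:(3 + n_r)]) else rep(1, n - 2L))
    w <- dfe_weights(grid, beta, gmean)
    if (is.null(w)) return(-Inf)
    Ef <- as.vector(grid$E %*% w)
    mu_neu <- theta_s * input$L_syn * r / ii
    mu_sel <- theta_s * input$L_nonsyn * r * Ef
    if (any(!is.finite(mu_neu)) || any(!is.finite(mu_sel)) ||
        any(mu_neu <= 0) || any(mu_sel <= 0)) return(-Inf)
    sum(stats::dpois(neu, mu_neu, log = TRUE)) +
      sum(stats::dpois(sel, mu_sel, log = TRUE))
  }
  lb <- log(c(bounds$theta_s[1], bounds$beta[1], bounds$gmean[1],
              rep(bounds$r[1], n_r)))
  ub <- log(c(bounds$theta_s[2], bounds$beta[2], bounds$gmean[2],
              rep(bounds$r[2], n_r)))
  ## uniform prior on the natural scale + log-scale walk => Jacobian sum(p)
  logpost <- function(p) {
    if (any(p < lb) || any(p > ub)) return(-Inf)
    loglik(p) + sum(p)
  }
  npar <- 3L + n_r
  init <- pmin(pmax(log(c(sum(neu) / (input$L_syn * sum(1 / ii)),
                          0.3, 100, rep(1, n_r))), lb + 0.01), ub - 0.01)
  with_seed(seed, {
    p <- init
    lp <- logpost(p)
    total <- burn_in + n_iter
    keep <- matrix(NA_real_, n_iter, npar)
    acc <- 0L; tries <- 0L
    for (it in seq_len(total)) {
      for (j in seq_len(npar)) {
        prop <- p
        prop[j] <- p[j] + stats::rnorm(1, 0, step)
        lp2 <- logpost(prop)
        tries <- tries + 1L
        if (log(stats::runif(1)) < lp2 - lp) { p <- prop; lp <- lp2; acc <- acc + 1L }
      }
      if (it > burn_in) keep[it - burn_in, ] <- p
    }
    ## alpha per retained draw
    alpha_draws <- apply(keep, 1, function(pp) {
      w <- dfe_weights(grid, exp(pp[2]), exp(pp[3]))
      ufix <- sum(w * grid$u)
      1 - input$D_s * (input$L_nonsyn / input$L_syn) * ufix /
        max(input$D_n, 1)
    })
    ci <- unname(stats::quantile(alpha_draws, c(0.025, 0.975)))
    ## split R-hat on the alpha chain
    half <- n_iter %/% 2L
    c1 <- alpha_draws[seq_len(half)]; c2 <- alpha_draws[half + seq_len(half)]
    W <- (stats::var(c1) + stats::var(c2)) / 2
    B <- half * (mean(c1) - mean(c2))^2 / 2 * 2
    rhat <- if (W > 0) sqrt((W * (half - 1) / half + B / half) / W) else 1
    diagnostics <- list(acceptance_rate = acc / tries, rhat_alpha = rhat)
    if (is.finite(rhat) && rhat > 1.1)
      warning(sprintf("alpha chain split R-hat %.3f > 1.1: chain may not have mixed",
                      rhat))
    structure(list(
      alpha = stats::median(alpha_draws), alpha_ci = ci,
      alpha_draws = alpha_draws,
      beta = mean(exp(keep[, 2])), gmean = mean(exp(keep[, 3])),
      theta_s = mean(exp(keep[, 1])),
      r = if (n_r) colMeans(exp(keep[, 4:(3 + n_r), drop = FALSE])) else
        rep(1, n - 2L),
      chain = keep, diagnostics = diagnostics, n = n
    ), class = "dfe_fit")
  })
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf("DFE fit (n=%d): alpha = %.3f (95%% CrI %.3f-%.3f), beta = %.2f, E|gamma| = %.1f\n",
              x$n, x$alpha, x$alpha_ci[1], x$alpha_ci[2], x$beta, x$gmean))
  invisible(x)
}

#' Simulate SFS and divergence data from the DFE model
#'
#' Poisson draws from the model's own expectations; adaptive divergence is
#' added so the generative alpha equals `alpha_true`.
#'
#' @param beta,gmean Gamma DFE shape and mean deleterious magnitude
#'   `E[-gamma]`.
#' @param alpha_true Target proportion of adaptive selected fixations.
#' @param theta_s Per-site neutral mutation parameter.
#' @param L_syn,L_nonsyn Class site totals.
#' @param n Sample size.
#' @param t_div Divergence scaling (expected neutral fixations per site =
#'   `theta_s * t_div`).
#' @param seed Integer seed.
#' @param grid Optional precomputed [dfe_grid()].
#' @return A `dfe_input` with attribute `truth`.
#' @export
simulate_dfe_data <- function(beta, gmean, alpha_true, theta_s,
                              L_syn, L_nonsyn, n, t_div = 10, seed = 1L,
                              grid = NULL) {
  if (alpha_true < 0 || alpha_true >= 1)
    stop_sweepmk("sweepmk_config_error", "alpha_true must be in [0, 1)")
  grid <- grid %||% dfe_grid(n)
  w <- dfe_weights(grid, beta, gmean)
  Ef <- as.vector(grid$E %*% w)
  ufix <- sum(w * grid$u)
  ii <- seq_len(n - 1L)
  mu_neu <- theta_s * L_syn / ii
  mu_sel <- theta_s * L_nonsyn * Ef
  E_Ds <- theta_s * L_syn * t_div
  E_Dn_del <- theta_s * L_nonsyn * t_div * ufix
  D_adapt <- alpha_true / (1 - alpha_true) * E_Dn_del
  with_seed(seed, {
    out <- dfe_input(
      neutral_sfs = new_sfs(stats::rpois(n - 1L, mu_neu), n, "4-fold"),
      selected_sfs = new_sfs(stats::rpois(n - 1L, mu_sel), n, "0-fold"),
      D_s = stats::rpois(1, E_Ds),
      D_n = stats::rpois(1, E_Dn_del + D_adapt),
      L_syn = L_syn, L_nonsyn = L_nonsyn)
    attr(out, "truth") <- list(beta = beta, gmean = gmean,
                               alpha_true = alpha_true, theta_s = theta_s,
                               ufix = ufix)
    out
  })
}
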