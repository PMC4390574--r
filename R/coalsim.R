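## Hudson coalescent with recombination under three demographic scenarios,
## ms-style parameter conventions: time in units of 4*N0 generations, theta
## and rho per locus.

#' Demographic scenarios for the neutral coalescent
#'
#' Relative population size backwards in time, `N(t)/N0`:
#' * `constant`: size 1 throughout.
#' * `exponential_growth`: forward-time exponential growth at rate `rate`
#'   (ms `-G` convention, `N(t) = exp(-rate * t)` backwards); before
#'   `onset_time` (looking back past it) the size is frozen at
#'   `exp(-rate * onset_time)`.
#' * `bottleneck_3epoch`: piecewise sizes `1`, `n_mid`, `n_anc` with change
#'   times `t1 < t2` (large-small-large when `n_mid < 1 <= n_anc`).
#'
#' @param kind Scenario name.
#' @param rate Growth rate (exponential_growth), `>= 0`.
#' @param onset_time Backwards time at which growth started; `Inf` means
#'   growth extends indefinitely into the past.
#' @param n_mid,n_anc Relative sizes of the middle and ancient epochs.
#' @param t1,t2 Epoch change times (4N0 units), `0 < t1 < t2`.
#' @return A `demography` object.
#' @export
demography <- function(kind = c("constant", "exponential_growth",
                                "bottleneck_3epoch"),
                       rate = 0, onset_time = Inf,
                       n_mid = 1, n_anc = 1, t1 = 0.1, t2 = 0.2) {
  kind <- match.arg(kind)
  if (kind == "exponential_growth" && rate < 0)
    stop_sweepmk("sweepmk_config_error", "growth rate must be >= 0")
  if (kind == "bottleneck_3epoch") {
    if (n_mid <= 0 || n_anc <= 0)
      stop_sweepmk("sweepmk_config_error", "epoch sizes must be positive")
    if (!(t1 > 0 && t2 > t1))
      stop_sweepmk("sweepmk_config_error", "need 0 < t1 < t2")
  }
  structure(list(kind = kind, rate = rate, onset_time = onset_time,
                 n_mid = n_mid, n_anc = n_anc, t1 = t1, t2 = t2),
            class = "demography")
}

## Coalescent intensity Lambda(t) = integral_0^t dt' / lambda(t') and its
## inverse, where lambda is the relative size. Coalescence waiting times are
## drawn in scaled time and mapped back through the inverse.
dem_intensity <- function(dem, t) {
  switch(dem$kind,
    constant = t,
    exponential_growth = {
      r <- dem$rate
      if (r == 0) return(t)
      Ton <- dem$onset_time
      if (t <= Ton) (exp(r * t) - 1) / r
      else (exp(r * Ton) - 1) / r + (t - Ton) * exp(r * Ton)
    },
    bottleneck_3epoch = {
      if (t <= dem$t1) t
      else if (t <= dem$t2) dem$t1 + (t - dem$t1) / dem$n_mid
      else dem$t1 + (dem$t2 - dem$t1) / dem$n_mid + (t - dem$t2) / dem$n_anc
    })
}

dem_intensity_inv <- function(dem, u) {
  switch(dem$kind,
    constant = u,
    exponential_growth = {
      r <- dem$rate
      if (r == 0) return(u)
      Ton <- dem$onset_time
      u_on <- if (is.finite(Ton)) (exp(r * Ton) - 1) / r else Inf
      if (u <= u_on) log1p(r * u) / r
      else Ton + (u - u_on) / exp(r * Ton)
    },
    bottleneck_3epoch = {
      u1 <- dem$t1
      u2 <- u1 + (dem$t2 - dem$t1) / dem$n_mid
      if (u <= u1) u
      else if (u <= u2) dem$t1 + (u - u1) * dem$n_mid
      else dem$t2 + (u - u2) * dem$n_anc
    })
}

## ---- interval-set helpers (2-column matrices of half-open [a, b)) ----

iv_length <- function(iv) if (!nrow(iv)) 0 else sum(iv[, 2] - iv[, 1])

iv_union <- function(a, b) {
  m <- rbind(a, b)
  if (!nrow(m)) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else out <- rbind(out, m[i, ])
  }
  out
}

iv_split <- function(iv, b) {
  left <- iv[iv[, 1] < b, , drop = FALSE]
  if (nrow(left)) left[, 2] <- pmin(left[, 2], b)
  right <- iv[iv[, 2] > b, , drop = FALSE]
  if (nrow(right)) right[, 1] <- pmax(right[, 1], b)
  list(left = left, right = right)
}

## parts of `a` overlapped by `b`
iv_intersect <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a[0, , drop = FALSE])
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (lo < hi) out <- rbind(out, c(lo, hi))
  }
  if (is.null(out)) a[0, , drop = FALSE] else out
}

iv_setdiff <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a)
  out <- NULL
  for (i in seq_len(nrow(a))) {
    pieces <- matrix(a[i, ], 1)
    for (j in seq_len(nrow(b))) {
      nxt <- NULL
      for (k in seq_len(nrow(pieces))) {
        lo <- pieces[k, 1]; hi <- pieces[k, 2]
        cl <- max(lo, b[j, 1]); ch <- min(hi, b[j, 2])
        if (cl >= ch) { nxt <- rbind(nxt, pieces[k, ]); next }
        if (lo < cl) nxt <- rbind(nxt, c(lo, cl))
        if (ch < hi) nxt <- rbind(nxt, c(ch, hi))
      }
      pieces <- if (is.null(nxt)) a[0, , drop = FALSE] else nxt
      if (!nrow(pieces)) break
    }
    out <- rbind(out, pieces)
  }
  if (is.null(out)) a[0, , drop = FALSE] else out
}

#' Simulate a neutral coalescent sample
#'
#' Hudson's algorithm: exponential coalescence waiting times rescaled
#' through the demographic intensity, recombination on the ancestral
#' recombination graph at rate `rho_locus/2` per unit span, and
#' infinite-sites mutations dropped on each marginal tree at rate
#' `theta_locus/2` per unit branch length.
#'
#' @param n Haploid sample size (`>= 2`).
#' @param theta_locus Population mutation rate for the whole locus.
#' @param dem A `demography` (default constant size).
#' @param rho_locus Population recombination rate for the locus (default 0).
#' @param seed Integer seed; results are reproducible.
#' @param locus_length_bp Physical length used to map positions to bp.
#' @return A `haplotype_matrix`: 0/1 matrix (`n` rows, one column per
#'   segregating site), sorted `positions` in `[0, 1)`, `locus_length_bp`.
#' @export
simulate_coalescent <- function(n, theta_locus, dem = demography("constant"),
                                rho_locus = 0, seed = 1L,
                                locus_length_bp = 1000L) {
  if (n < 2L) stop_sweepmk("sweepmk_config_error", "n must be >= 2")
  if (theta_locus <= 0) stop_sweepmk("sweepmk_config_error", "theta must be > 0")
  if (rho_locus < 0) stop_sweepmk("sweepmk_config_error", "rho must be >= 0")
  if (!inherits(dem, "demography"))
    stop_sweepmk("sweepmk_config_error", "dem must be a demography object")
  with_seed(seed, {
    full <- matrix(c(0, 1), 1)
    lineages <- lapply(seq_len(n), function(i)
      list(id = i, birth = 0, material = full))
    next_id <- n + 1L
    events <- list()
    t <- 0
    while (length(lineages) >= 2L) {
      k <- length(lineages)
      spans <- vapply(lineages, function(l)
        max(l$material[, 2]) - min(l$material[, 1]), numeric(1))
      R <- (rho_locus / 2) * sum(spans)
      t_r <- if (R > 0) t + stats::rexp(1) / R else Inf
      w <- stats::rexp(1) / (k * (k - 1) / 2)
      t_c <- dem_intensity_inv(dem, dem_intensity(dem, t) + w)
      if (t_r < t_c) {
        t <- t_r
        li <- sample.int(k, 1L, prob = spans)
        lin <- lineages[[li]]
        b <- stats::runif(1, min(lin$material[, 1]), max(lin$material[, 2]))
        sp <- iv_split(lin$material, b)
        if (!nrow(sp$left) || !nrow(sp$right)) next  # breakpoint outside material
        idl <- next_id; idr <- next_id + 1L; next_id <- next_id + 2L
        events[[length(events) + 1L]] <- list(
          type = "rec", time = t, child = lin$id,
          parent_left = idl, parent_right = idr, breakpoint = b)
        lineages[[li]] <- list(id = idl, birth = t, material = sp$left)
        lineages[[length(lineages) + 1L]] <-
          list(id = idr, birth = t, material = sp$right)
      } else {
        t <- t_c
        pick <- sample.int(k, 2L)
        l1 <- lineages[[pick[1]]]; l2 <- lineages[[pick[2]]]
        pid <- next_id; next_id <- next_id + 1L
        events[[length(events) + 1L]] <- list(
          type = "coal", time = t, child1 = l1$id, child2 = l2$id,
          parent = pid)
        mat <- iv_union(l1$material, l2$material)
        others <- lineages[-pick]
        if (length(others)) {
          other_mat <- Reduce(iv_union, lapply(others, `[[`, "material"))
          mat <- iv_intersect(mat, other_mat)  # drop segment-MRCA'd parts
        } else mat <- mat[0, , drop = FALSE]
        lineages <- c(others, if (nrow(mat))
          list(list(id = pid, birth = t, material = mat)))
      }
    }
    ## marginal trees per recombination segment, then mutations
    bps <- sort(unique(vapply(Filter(function(e) e$type == "rec", events),
                              `[[`, numeric(1), "breakpoint")))
    bounds <- unique(c(0, bps, 1))
    positions <- numeric(0)
    carriers <- list()
    for (si in seq_len(length(bounds) - 1L)) {
      lo <- bounds[si]; hi <- bounds[si + 1L]
      mid <- (lo + hi) / 2
      active <- lapply(seq_len(n), function(i)
        list(id = i, birth = 0, leaves = i))
      branches_len <- numeric(0); branches_leaves <- list()
      for (e in events) {
        if (length(active) <= 1L) break
        ids <- vapply(active, `[[`, numeric(1), "id")
        if (e$type == "rec") {
          hit <- which(ids == e$child)
          if (length(hit))
            active[[hit]]$id <- if (mid < e$breakpoint) e$parent_left
                                else e$parent_right
        } else {
          h1 <- which(ids == e$child1); h2 <- which(ids == e$child2)
          if (length(h1) && length(h2)) {
            for (h in c(h1, h2)) {
              branches_len <- c(branches_len, e$time - active[[h]]$birth)
              branches_leaves[[length(branches_leaves) + 1L]] <-
                active[[h]]$leaves
            }
            merged <- list(id = e$parent, birth = e$time,
                           leaves = sort(c(active[[h1]]$leaves,
                                           active[[h2]]$leaves)))
            active <- c(active[-c(h1, h2)], list(merged))
          } else if (length(h1)) {
            active[[h1]]$id <- e$parent
          } else if (length(h2)) {
            active[[h2]]$id <- e$parent
          }
        }
      }
      Tseg <- sum(branches_len)
      n_mut <- stats::rpois(1, theta_locus / 2 * Tseg * (hi - lo))
      if (n_mut > 0) {
        br <- sample.int(length(branches_len), n_mut, replace = TRUE,
                         prob = branches_len)
        pos <- stats::runif(n_mut, lo, hi)
        positions <- c(positions, pos)
        carriers <- c(carriers, branches_leaves[br])
      }
    }
    ord <- order(positions)
    S <- length(positions)
    mat <- matrix(0L, n, S)
    for (j in seq_len(S)) mat[carriers[[ord[j]]], j] <- 1L
    structure(list(mat = mat, positions = positions[ord], n = n,
                   locus_length_bp = as.integer(locus_length_bp)),
              class = "haplotype_matrix")
  })
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: n=%d, S=%d, locus=%d bp\n",
              x$n, ncol(x$mat), x$locus_length_bp))
  invisible(x)
}

#' Summary statistics of a haplotype matrix
#' @param hm A `haplotype_matrix`.
#' @return List with `S` (segregating sites), `pi` (mean pairwise
#'   difference count over the locus) and the unfolded SFS counts.
#' @export
summarize_haplotypes <- function(hm) {
  n <- hm$n
  dac <- colSums(hm$mat)
  pi <- if (length(dac)) sum(dac * (n - dac)) / (n * (n - 1) / 2) else 0
  list(S = ncol(hm$mat), pi = pi,
       sfs = new_sfs(tabulate(dac, nbins = n - 1L), n))
}

#' Draw demographic and mutation parameters from uniform priors
#'
#' @param prior_spec Named list of length-2 numeric ranges, e.g.
#'   `list(theta_per_site = c(0.006, 0.009), rate = c(0, 100))`.
#' @param n_draws Number of replicates.
#' @param seed Integer seed.
#' @return Data frame with one column per parameter, `n_draws` rows.
#' @export
draw_priors <- function(prior_spec, n_draws, seed = 1L) {
  for (nm in names(prior_spec)) {
    r <- prior_spec[[nm]]
    if (length(r) != 2L || r[1] > r[2])
      stop_sweepmk("sweepmk_config_error", "invalid prior range for %s", nm)
  }
  with_seed(seed, {
    as.data.frame(lapply(prior_spec, function(r)
      stats::runif(n_draws, r[1], r[2])))
  })
}

## Build a demography object for one prior draw of a given scenario kind.
dem_from_draw <- function(kind, draw) {
  switch(kind,
    constant = demography("constant"),
    exponential_growth = demography("exponential_growth",
                                    rate = draw[["rate"]] %||% 0,
                                    onset_time = draw[["onset_time"]] %||% Inf),
    bottleneck_3epoch = demography("bottleneck_3epoch",
                                   n_mid = draw[["n_mid"]] %||% 1,
                                   n_anc = draw[["n_anc"]] %||% 1,
                                   t1 = draw[["t1"]] %||% 0.1,
                                   t2 = draw[["t2"]] %||% 0.2))
}

#' Null distribution of a scan statistic under neutral simulations
#'
#' For each replicate, draws parameters from the uniform priors, simulates
#' a neutral sample under the requested demography and evaluates the scan
#' statistic with the same settings used on real data.
#'
#' @param statistic `"max_CLR"` or `"max_omega"`.
#' @param prior_spec Uniform prior ranges; must contain `theta_per_site`,
#'   may contain demographic parameter ranges (`rate`, `onset_time`,
#'   `n_mid`, `n_anc`, `t1`, `t2`).
#' @param demography_kind Scenario simulated for every replicate.
#' @param n Sample size; `locus_length` in bp.
#' @param n_sims Number of replicates (`>= 100`).
#' @param seed Integer seed.
#' @param rho_per_site Optional recombination rate per site (default 0).
#' @param scan_args List of extra arguments passed to the scan function.
#' @param max_retries Resimulation attempts when a replicate cannot be
#'   evaluated (e.g. too few segregating sites).
#' @return A `null_distribution` list: sorted `values`, `statistic`,
#'   `n_failures`, `seed`, `spec_hash`.
#' @export
null_distribution <- function(statistic = c("max_CLR", "max_omega"),
                              prior_spec, demography_kind = "constant",
                              n, locus_length, n_sims = 1000L, seed = 1L,
                              rho_per_site = 0, scan_args = list(),
                              max_retries = 20L) {
  statistic <- match.arg(statistic)
  if (n_sims < 100L)
    stop_sweepmk("sweepmk_config_error", "n_sims must be >= 100")
  draws <- draw_priors(prior_spec, n_sims, seed = derive_seed(seed, 0L))
  vals <- numeric(n_sims)
  n_fail <- 0L
  for (i in seq_len(n_sims)) {
    draw <- as.list(draws[i, , drop = FALSE])
    ok <- FALSE
    for (retry in 0:max_retries) {
      sim_seed <- derive_seed(seed, i * (max_retries + 1L) + retry)
      hm <- simulate_coalescent(
        n, theta_locus = draw$theta_per_site * locus_length,
        dem = dem_from_draw(demography_kind, draw),
        rho_locus = rho_per_site * locus_length,
        seed = sim_seed, locus_length_bp = locus_length)
      v <- tryCatch(
        if (statistic == "max_CLR")
          do.call(clr_scan, c(list(hm), scan_args))$max_CLR
        else do.call(omega_max, c(list(hm), scan_args))$max_omega,
        sweepmk_error = function(e) NA_real_)
      if (!is.na(v)) { vals[i] <- v; ok <- TRUE; break }
    }
    if (!ok) { n_fail <- n_fail + 1L; vals[i] <- NA_real_ }
  }
  vals <- sort(vals[!is.na(vals)])
  structure(list(values = vals, statistic = statistic,
                 n_failures = n_fail, seed = seed,
                 spec_hash = paste(demography_kind, n, locus_length, n_sims,
                                   paste(unlist(prior_spec), collapse = ","),
                                   sep = "|")),
            class = "null_distribution")
}

#' Write haplotype replicates in ms format
#' @param reps List of `haplotype_matrix` objects.
#' @param path Output file.
#' @param command Header line (first line of the file).
#' @export
write_ms <- function(reps, path, command = "sweepmk simulate") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(command, "0 0 0", ""), con)
  for (hm in reps) {
    writeLines("//", con)
    S <- ncol(hm$mat)
    writeLines(sprintf("segsites: %d", S), con)
    if (S > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", hm$positions), collapse = " ")),
                 con)
      writeLines(apply(hm$mat, 1, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read ms-format haplotype replicates
#' @param path An ms-format text file.
#' @param n Sample size (rows per replicate); inferred if `NULL`.
#' @param locus_length_bp Physical length attached to each replicate.
#' @return List of `haplotype_matrix` objects.
#' @export
read_ms <- function(path, n = NULL, locus_length_bp = 1000L) {
  lines <- readLines(path)
  starts <- which(lines == "//")
  reps <- list()
  for (s in starts) {
    seg <- as.integer(sub("segsites: *", "", lines[s + 1L]))
    if (seg == 0L) {
      nn <- n %||% 2L
      reps[[length(reps) + 1L]] <- structure(
        list(mat = matrix(0L, nn, 0), positions = numeric(0), n = nn,
             locus_length_bp = as.integer(locus_length_bp)),
        class = "haplotype_matrix")
      next
    }
    pos <- as.numeric(strsplit(sub("positions: *", "", lines[s + 2L]),
                               " +")[[1]])
    i <- s + 3L
    hap <- character(0)
    while (i <= length(lines) && grepl("^[01]+$", lines[i])) {
      hap <- c(hap, lines[i]); i <- i + 1L
    }
    mat <- do.call(rbind, lapply(strsplit(hap, ""), as.integer))
    reps[[length(reps) + 1L]] <- structure(
      list(mat = mat, positions = pos, n = nrow(mat),
           locus_length_bp = as.integer(locus_length_bp)),
      class = "haplotype_matrix")
  }
  reps
}
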