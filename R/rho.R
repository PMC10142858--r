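# --- two-locus coalescent simulation -------------------------------------
#
# Simulates the genealogy of two linked loci for n samples with scaled
# recombination rate C between them, tracking per-locus descendant sets.
# One mutation per locus is then dropped uniformly on the marginal tree
# (branch length-weighted, root-spanning segments excluded), which
# conditions on both loci being biallelic and segregating -- the small-theta
# limit used for composite-likelihood lookup tables.  Returns the haplotype
# counts (n_AB, n_Ab, n_aB, n_ab), where A/B denote the mutant allele.
.popcount <- function(m) {
  cnt <- 0L
  while (m > 0L) { cnt <- cnt + bitwAnd(m, 1L); m <- bitwShiftR(m, 1L) }
  cnt
}

.sim_two_locus_config <- function(n, C) {
  if (n > 30L) stop("two-locus simulation supports n <= 30")
  # descendant sets as integer bitmasks; 0 = no material at that locus
  lin_a <- bitwShiftL(1L, 0:(n - 1L))
  lin_b <- lin_a
  full <- bitwShiftL(1L, n) - 1L
  keys_a <- integer(0); ts_a <- numeric(0)   # per-set branch-time tallies
  keys_b <- integer(0); ts_b <- numeric(0)
  repeat {
    k <- length(lin_a)
    if (k <= 1L) break
    both <- lin_a != 0L & lin_b != 0L
    rate_c <- k * (k - 1) / 2
    rate_r <- C / 2 * sum(both)
    dt <- stats::rexp(1L, rate_c + rate_r)
    am <- lin_a[lin_a != 0L]
    ia <- match(am, keys_a)
    new <- is.na(ia)
    if (any(new)) {
      keys_a <- c(keys_a, am[new]); ts_a <- c(ts_a, numeric(sum(new)))
      ia <- match(am, keys_a)
    }
    ts_a[ia] <- ts_a[ia] + dt
    bm <- lin_b[lin_b != 0L]
    ib <- match(bm, keys_b)
    new <- is.na(ib)
    if (any(new)) {
      keys_b <- c(keys_b, bm[new]); ts_b <- c(ts_b, numeric(sum(new)))
      ib <- match(bm, keys_b)
    }
    ts_b[ib] <- ts_b[ib] + dt
    if (stats::runif(1L) < rate_c / (rate_c + rate_r)) {
      pair <- sample.int(k, 2L)
      i <- pair[1L]; j <- pair[2L]
      na <- bitwOr(lin_a[i], lin_a[j])
      nb <- bitwOr(lin_b[i], lin_b[j])
      if (na == full) na <- 0L                  # locus reached its MRCA
      if (nb == full) nb <- 0L
      lin_a[i] <- na; lin_b[i] <- nb
      lin_a <- lin_a[-j]; lin_b <- lin_b[-j]
      keep <- lin_a != 0L | lin_b != 0L
      lin_a <- lin_a[keep]; lin_b <- lin_b[keep]
    } else {
      # split: the new lineage takes the locus-A material, the original
      # lineage keeps locus B
      cand <- which(both)
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      lin_a <- c(lin_a, lin_a[j]); lin_b <- c(lin_b, 0L)
      lin_a[j] <- 0L
    }
  }
  draw <- function(keys, ts) {
    if (length(keys) == 1L) keys else sample(keys, 1L, prob = ts)
  }
  SA <- draw(keys_a, ts_a); SB <- draw(keys_b, ts_b)
  nAB <- .popcount(bitwAnd(SA, SB))
  nA <- .popcount(SA); nB <- .popcount(SB)
  c(nAB = nAB, nAb = nA - nAB, naB = nB - nAB, nab = n - nA - nB + nAB)
}

# canonical form of a two-locus sample configuration: minimum over allele
# relabelling at each locus and locus exchange (8 symmetries).  Vectorized
# over configurations; counts are zero-padded so string order = numeric
# order.
.canonical_config_vec <- function(nAB, nAb, naB, nab) {
  forms <- list(
    cbind(nAB, nAb, naB, nab), cbind(naB, nab, nAB, nAb),  # flip locus A
    cbind(nAb, nAB, nab, naB), cbind(nab, naB, nAb, nAB),  # flip B / both
    cbind(nAB, naB, nAb, nab), cbind(nAb, nab, nAB, naB),  # locus swap x flips
    cbind(naB, nAB, nab, nAb), cbind(nab, nAb, naB, nAB))
  keys <- lapply(forms, function(f)
    sprintf("%03d/%03d/%03d/%03d", f[, 1L], f[, 2L], f[, 3L], f[, 4L]))
  out <- keys[[1L]]
  for (i in 2:8) out <- pmin(out, keys[[i]])
  out
}

.canonical_config <- function(cf) {
  .canonical_config_vec(cf[[1L]], cf[[2L]], cf[[3L]], cf[[4L]])
}

#' Build a two-locus likelihood lookup table by coalescent simulation
#'
#' For each value of the scaled recombination rate C on `rho_grid`,
#' simulates `n_sims` two-locus genealogies for `n` samples and tabulates
#' the probability of each canonical sample configuration (both loci
#' segregating, infinite sites). Composite-likelihood estimation of rho
#' interpolates this table at C = rho * distance for every site pair.
#' Configurations never observed at a gridpoint receive a pseudocount floor
#' of `0.5 / n_sims` so composite log-likelihoods stay finite.
#'
#' @param n Sample size (>= 2); must match the data the table will score.
#' @param theta_site Per-site theta recorded as metadata (the conditional
#'   single-mutation placement makes the table itself theta-free, the
#'   small-theta limit appropriate for theta on the order of 0.003).
#' @param rho_grid Sorted grid of C values starting at 0 (default: 0 plus
#'   100 geometric points from 0.1 to 100).
#' @param n_sims Monte Carlo replicates per gridpoint.
#' @param seed Optional integer seed.
#' @return An object of class `mt_lookup`: list with `n`, `theta_site`,
#'   `rho_grid`, `loglik` (matrix: canonical configs x gridpoints),
#'   `floor_log`, `n_sims`, `seed`.
#' @export
build_two_locus_table <- function(n, theta_site = 0.003,
                                  rho_grid = NULL, n_sims = 1000L,
                                  seed = NULL) {
  if (n < 2L) stop("n must be >= 2")
  if (is.null(rho_grid))
    rho_grid <- c(0, exp(seq(log(0.1), log(100), length.out = 100L)))
  if (is.unsorted(rho_grid) || rho_grid[1L] != 0)
    stop("rho_grid must be sorted with first point 0")
  if (!is.null(seed)) set.seed(seed)
  counts <- list()
  for (g in seq_along(rho_grid)) {
    tab <- new.env(parent = emptyenv())
    for (s in seq_len(n_sims)) {
      key <- .canonical_config(.sim_two_locus_config(n, rho_grid[g]))
      tab[[key]] <- (if (is.null(tab[[key]])) 0L else tab[[key]]) + 1L
    }
    counts[[g]] <- tab
  }
  keys <- sort(unique(unlist(lapply(counts, ls))))
  if (length(keys) == 0L)
    stop("no segregating configurations observed; increase n_sims")
  floor_log <- log(0.5 / n_sims)
  ll <- matrix(floor_log, length(keys), length(rho_grid),
               dimnames = list(keys, NULL))
  for (g in seq_along(rho_grid))
    for (key in ls(counts[[g]]))
      ll[key, g] <- log(counts[[g]][[key]] / n_sims)
  structure(list(n = as.integer(n), theta_site = theta_site,
                 rho_grid = rho_grid, loglik = ll, floor_log = floor_log,
                 n_sims = as.integer(n_sims), seed = seed),
            class = "mt_lookup")
}

#' @export
print.mt_lookup <- function(x, ...) {
  cat(sprintf("mt_lookup: n = %d, %d configs x %d gridpoints (C in [0, %g], %d sims each)\n",
              x$n, nrow(x$loglik), length(x$rho_grid), max(x$rho_grid),
              x$n_sims))
  invisible(x)
}

# Factory: composite log-likelihood as a function of the per-pair scaled
# rates C; linear interpolation on the grid, flat beyond the last gridpoint.
# Configs absent from the table sit at the pseudocount floor.
.cl_from_C <- function(table, keys) {
  row <- match(keys, rownames(table$loglik))
  miss <- is.na(row)
  row[miss] <- 1L
  grid <- table$rho_grid
  ll <- table$loglik
  G <- length(grid)
  floor_term <- sum(miss) * table$floor_log
  row <- row[!miss]
  function(C) {
    C <- pmin(C[!miss], grid[G])
    idx <- findInterval(C, grid)
    idx[idx >= G] <- G - 1L
    w <- (C - grid[idx]) / (grid[idx + 1L] - grid[idx])
    v <- ll[cbind(row, idx)] * (1 - w) + ll[cbind(row, idx + 1L)] * w
    sum(v) + floor_term
  }
}

# log-likelihood of canonical configs at scaled rates C (vector interface)
.lookup_loglik <- function(table, keys, C) {
  out <- numeric(length(keys))
  row <- match(keys, rownames(table$loglik))
  miss <- is.na(row)
  out[miss] <- table$floor_log
  if (any(!miss)) {
    grid <- table$rho_grid
    G <- length(grid)
    Cc <- pmin(C[!miss], grid[G])
    idx <- findInterval(Cc, grid)
    idx[idx >= G] <- G - 1L
    w <- (Cc - grid[idx]) / (grid[idx + 1L] - grid[idx])
    r <- row[!miss]
    out[!miss] <- table$loglik[cbind(r, idx)] * (1 - w) +
      table$loglik[cbind(r, idx + 1L)] * w
  }
  out
}

# canonical config keys, distances and site indices for all scorable pairs
# (complete cases matching the table's n, both loci biallelic)
.pair_configs <- function(sites, table, circular) {
  G <- sites$geno
  S <- ncol(G)
  if (S < 2L) stop("no biallelic site pairs")
  pos <- sites$sites$pos
  pc <- .pair_counts(G)
  ut <- which(upper.tri(pc$n11), arr.ind = TRUE)
  n11 <- pc$n11[ut]; n10 <- pc$n10[ut]
  n01 <- pc$n01[ut]; n00 <- pc$n00[ut]
  keep <- pc$complete[ut] == table$n &
    (n11 + n10) > 0 & (n01 + n00) > 0 & (n11 + n01) > 0 & (n10 + n00) > 0
  if (!any(keep)) stop("estimation error: no usable site pairs")
  ii <- ut[keep, 1L]; jj <- ut[keep, 2L]
  keys <- .canonical_config_vec(n11[keep], n10[keep], n01[keep], n00[keep])
  d <- abs(pos[jj] - pos[ii])
  if (circular) d <- pmin(d, sites$alignment_length - d)
  list(keys = keys, dists = d, i = ii, j = jj)
}

#' Watterson's theta per site
#' @param sites An `mt_sites`.
#' @return Per-site theta_w = S / (L * sum_{i=1}^{n-1} 1/i).
#' @export
theta_watterson <- function(sites) {
  n <- length(sites$sample_ids)
  n_sites(sites) / (sites$alignment_length * sum(1 / seq_len(n - 1L)))
}

# per-site pi from allele frequencies (unbiased pairwise heterozygosity)
.pi_from_sites <- function(sites) {
  G <- sites$geno
  n <- nrow(G)
  p <- colMeans(G, na.rm = TRUE)
  sum(2 * p * (1 - p) * n / (n - 1)) / sites$alignment_length
}

#' Composite-likelihood estimate of a constant recombination rate
#'
#' Maximizes the composite log-likelihood CL(rho) = sum over biallelic site
#' pairs of log P(config | C = rho * d) over the lookup table, with d the
#' pair distance (minimum circular arc when the data are circular). Also
#' reports the recombination-to-mutation ratio r/m both as rho/theta_w
#' (Watterson) and rho/pi.
#'
#' @param sites An `mt_sites` whose complete-case sample count matches
#'   `table$n` (pairs with missing samples are skipped).
#' @param table An `mt_lookup` built with [build_two_locus_table()].
#' @param circular Override the circularity flag of `sites` (optional).
#' @return List of class `mt_rho` with `rho_site`, `r_over_m`
#'   (list: `rho_over_theta_w`, `rho_over_pi`), `n_pairs`, `cl_max` and the
#'   profile (`rho_profile`, `cl_profile`).
#' @export
estimate_constant_rho <- function(sites, table, circular = NULL) {
  stopifnot(inherits(sites, "mt_sites"), inherits(table, "mt_lookup"))
  if (is.null(circular)) circular <- isTRUE(sites$circular)
  pc <- .pair_configs(sites, table, circular)
  cl_C <- .cl_from_C(table, pc$keys)
  cl_of <- function(rho) cl_C(rho * pc$dists)
  d_min <- max(1, min(pc$dists)); d_max <- max(pc$dists)
  hi <- max(table$rho_grid) / d_min
  lo <- min(table$rho_grid[table$rho_grid > 0]) / d_max / 10
  cand <- c(0, exp(seq(log(lo), log(hi), length.out = 80L)))
  cl <- vapply(cand, cl_of, numeric(1))
  best <- which.max(cl)
  rho_hat <- cand[best]
  if (best > 1L && best < length(cand)) {  # refine inside the bracket
    opt <- stats::optimize(cl_of, c(cand[best - 1L], cand[best + 1L]),
                           maximum = TRUE, tol = lo)
    if (opt$objective >= cl[best]) rho_hat <- opt$maximum
  }
  tw <- theta_watterson(sites)
  pi_hat <- .pi_from_sites(sites)
  structure(list(rho_site = rho_hat,
                 r_over_m = list(rho_over_theta_w = if (tw > 0) rho_hat / tw else NA_real_,
                                 rho_over_pi = if (pi_hat > 0) rho_hat / pi_hat else NA_real_),
                 n_pairs = length(pc$keys), cl_max = max(cl),
                 rho_profile = cand, cl_profile = cl),
            class = "mt_rho")
}

#' Variable recombination-rate map by reversible-jump MCMC
#'
#' Samples piecewise-constant per-site recombination maps with change
#' points at segregating sites. The composite likelihood scores every site
#' pair at C = (cumulative map integral between the sites); the prior is
#' exponential on block rates and penalizes each change point by
#' `block_penalty` (on the natural-log scale), favouring smooth maps. The
#' posterior is summarized per window as the mean and central 95% credible
#' interval of the windowed average rate.
#'
#' @param sites An `mt_sites` (complete cases must match `table$n`).
#' @param table An `mt_lookup`.
#' @param block_penalty Change-point penalty (default 5).
#' @param n_iter Total MCMC iterations (default 1e5, a desk-scale setting;
#'   1e6 with `thin = 5000` reproduces survey-scale runs).
#' @param thin Record every `thin`-th iteration after burn-in.
#' @param burnin_fraction Fraction of `n_iter` discarded as burn-in.
#' @param window Summary window width in bp (default 2000).
#' @param seed Optional integer seed.
#' @return List of class `mt_rhomap` with `windows` (data.frame `start`,
#'   `end`, `mean_rho`, `ci_low`, `ci_high`), `global_mean_rho`,
#'   `r_over_m`, `n_retained`, `acceptance`, `n_changepoints` (posterior
#'   draws) and `mixing_warning`.
#' @export
estimate_variable_rho <- function(sites, table, block_penalty = 5,
                                  n_iter = 1e5L, thin = 500L,
                                  burnin_fraction = 0.25, window = 2000L,
                                  seed = NULL) {
  stopifnot(inherits(sites, "mt_sites"), inherits(table, "mt_lookup"))
  if (n_iter < thin) stop("n_iter must be >= thin")
  if (!is.null(seed)) set.seed(seed)
  pos <- sites$sites$pos
  S <- length(pos)
  if (S < 3L) stop("need >= 3 sites for a rate map")
  pc <- .pair_configs(sites, table, circular = FALSE)
  ii <- pc$i; jj <- pc$j
  cl_C <- .cl_from_C(table, pc$keys)
  loglik_of_R <- function(Rcum) cl_C(Rcum[jj] - Rcum[ii])
  gaps <- diff(pos)                       # lengths of the S-1 inter-site gaps
  span <- pos[S] - pos[1L]
  # state: change points = subset of gap boundaries (after site cp_idx);
  # blocks partition gaps; log-rates per block
  init_rho <- {
    cr <- tryCatch(estimate_constant_rho(sites, table)$rho_site,
                   error = function(e) 0)
    max(cr, 1e-6)
  }
  mu <- init_rho                          # prior mean for block rates
  cps <- integer(0)                       # sorted gap indices (1..S-2) with a break AFTER gap
  logr <- log(init_rho)                   # per-block log rates
  rcum_of <- function(cps, logr) {
    block_of_gap <- findInterval(seq_len(S - 1L), cps + 0.5) + 1L
    c(0, cumsum(gaps * exp(logr)[block_of_gap]))
  }
  cur_R <- rcum_of(cps, logr)
  cur_ll <- loglik_of_R(cur_R)
  log_prior <- function(cps, logr) {
    r <- exp(logr)
    sum(stats::dexp(r, 1 / mu, log = TRUE)) - block_penalty * length(cps)
  }
  cur_lp <- log_prior(cps, logr)
  sigma_rate <- 0.6; sigma_birth <- 1.0
  acc <- c(rate = 0L, birth = 0L, death = 0L)
  tried <- c(rate = 0L, birth = 0L, death = 0L)
  burnin <- floor(n_iter * burnin_fraction)
  win_starts <- seq(0L, sites$alignment_length - 1L, by = window)
  win_ends <- pmin(win_starts + window, sites$alignment_length)
  win_mean_of <- function(cps, logr) {
    # piecewise-constant map on [pos1, posS]; windows clipped to that span
    bm <- findInterval(seq_len(S - 1L), cps + 0.5) + 1L
    rates <- exp(logr)[bm]
    vapply(seq_along(win_starts), function(w) {
      a <- max(win_starts[w], pos[1L]); b <- min(win_ends[w], pos[S])
      if (b <= a) return(NA_real_)
      ov <- pmax(0, pmin(pos[-1L], b) - pmax(pos[-S], a))
      sum(ov * rates) / (b - a)
    }, numeric(1))
  }
  retained_win <- list(); retained_glob <- numeric(0)
  retained_K <- integer(0)
  for (it in seq_len(n_iter)) {
    u <- stats::runif(1L)
    K <- length(cps)
    if (u < 0.5) {                                   # rate update
      tried["rate"] <- tried["rate"] + 1L
      bsel <- sample.int(K + 1L, 1L)
      prop_logr <- logr
      prop_logr[bsel] <- prop_logr[bsel] + stats::rnorm(1L, 0, sigma_rate)
      prop_R <- rcum_of(cps, prop_logr)
      prop_ll <- loglik_of_R(prop_R)
      prop_lp <- log_prior(cps, prop_logr)
      # proposal symmetric in log space; include d(r)/d(log r) Jacobians
      lacc <- (prop_ll + prop_lp + prop_logr[bsel]) -
        (cur_ll + cur_lp + logr[bsel])
      if (log(stats::runif(1L)) < lacc) {
        logr <- prop_logr; cur_R <- prop_R; cur_ll <- prop_ll; cur_lp <- prop_lp
        acc["rate"] <- acc["rate"] + 1L
      }
    } else if (u < 0.75 || K == 0L) {                # birth
      tried["birth"] <- tried["birth"] + 1L
      free <- setdiff(seq_len(S - 2L), cps)
      if (length(free)) {
        cp_new <- if (length(free) == 1L) free else sample(free, 1L)
        prop_cps <- sort(c(cps, cp_new))
        bidx <- which(prop_cps == cp_new)            # new left block index
        old_block <- bidx                             # block being split
        r_old <- logr[old_block]
        # weight = share of the split block's gap length left of the break
        blocks_gaps <- findInterval(seq_len(S - 1L), cps + 0.5) + 1L
        in_block <- which(blocks_gaps == old_block)
        wL <- sum(gaps[in_block[in_block <= cp_new]]) / sum(gaps[in_block])
        wL <- min(max(wL, 1e-6), 1 - 1e-6)
        z <- stats::rnorm(1L, 0, sigma_birth)
        lr1 <- r_old + z * (1 - wL)
        lr2 <- r_old - z * wL
        prop_logr <- append(logr[-old_block], c(lr1, lr2), after = old_block - 1L)
        prop_R <- rcum_of(prop_cps, prop_logr)
        prop_ll <- loglik_of_R(prop_R)
        prop_lp <- log_prior(prop_cps, prop_logr)
        # rj factors: position choice, z density, log-space Jacobian 1,
        # r-space Jacobian r1*r2/r, death reverse picks 1 of K+1 breaks
        lacc <- (prop_ll + prop_lp) - (cur_ll + cur_lp) +
          log(length(free)) - log(K + 1L) -
          stats::dnorm(z, 0, sigma_birth, log = TRUE) +
          (lr1 + lr2 - r_old)
        if (log(stats::runif(1L)) < lacc) {
          cps <- prop_cps; logr <- prop_logr
          cur_R <- prop_R; cur_ll <- prop_ll; cur_lp <- prop_lp
          acc["birth"] <- acc["birth"] + 1L
        }
      }
    } else {                                         # death
      tried["death"] <- tried["death"] + 1L
      drop <- sample.int(K, 1L)
      cp_old <- cps[drop]
      prop_cps <- cps[-drop]
      lr1 <- logr[drop]; lr2 <- logr[drop + 1L]
      blocks_gaps_new <- findInterval(seq_len(S - 1L), prop_cps + 0.5) + 1L
      in_block <- which(blocks_gaps_new == drop)
      wL <- sum(gaps[in_block[in_block <= cp_old]]) / sum(gaps[in_block])
      wL <- min(max(wL, 1e-6), 1 - 1e-6)
      r_merged <- wL * lr1 + (1 - wL) * lr2
      z <- lr1 - r_merged
      prop_logr <- append(logr[-c(drop, drop + 1L)], r_merged,
                          after = drop - 1L)
      prop_R <- rcum_of(prop_cps, prop_logr)
      prop_ll <- loglik_of_R(prop_R)
      prop_lp <- log_prior(prop_cps, prop_logr)
      free_after <- (S - 2L) - (K - 1L)
      lacc <- (prop_ll + prop_lp) - (cur_ll + cur_lp) +
        log(K) - log(free_after) +
        stats::dnorm(z / (1 - wL), 0, sigma_birth, log = TRUE) +
        (r_merged - lr1 - lr2)
      if (log(stats::runif(1L)) < lacc) {
        cps <- prop_cps; logr <- prop_logr
        cur_R <- prop_R; cur_ll <- prop_ll; cur_lp <- prop_lp
        acc["death"] <- acc["death"] + 1L
      }
    }
    if (it > burnin && (it - burnin) %% thin == 0L) {
      retained_win[[length(retained_win) + 1L]] <- win_mean_of(cps, logr)
      retained_glob <- c(retained_glob, cur_R[S] / span)
      retained_K <- c(retained_K, length(cps))
    }
  }
  wm <- do.call(rbind, retained_win)
  windows <- data.frame(start = win_starts, end = win_ends,
                        mean_rho = colMeans(wm),
                        ci_low = apply(wm, 2L, stats::quantile, 0.025,
                                       na.rm = TRUE, names = FALSE),
                        ci_high = apply(wm, 2L, stats::quantile, 0.975,
                                        na.rm = TRUE, names = FALSE))
  tw <- theta_watterson(sites)
  pi_hat <- .pi_from_sites(sites)
  glob <- mean(retained_glob)
  acc_rate <- sum(acc) / max(1L, sum(tried))
  structure(list(windows = windows, global_mean_rho = glob,
                 r_over_m = list(rho_over_theta_w = if (tw > 0) glob / tw else NA_real_,
                                 rho_over_pi = if (pi_hat > 0) glob / pi_hat else NA_real_),
                 n_retained = length(retained_glob),
                 acceptance = acc / pmax(1L, tried),
                 n_changepoints = retained_K,
                 mixing_warning = acc_rate < 0.01),
            class = "mt_rhomap")
}
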