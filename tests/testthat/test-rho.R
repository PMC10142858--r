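# shared small lookup table for this file (built once; ~15 s)
local_table <- local({
  tab <- NULL
  function(n = 12L) {
    if (is.null(tab))
      tab <<- build_two_locus_table(
        n, rho_grid = c(0, exp(seq(log(0.05), log(100), length.out = 14))),
        n_sims = 800L, seed = 99)
    tab
  }
})

test_that("two-locus table respects coalescent structure", {
  tab <- local_table()
  keys <- rownames(tab$loglik)
  cfg <- do.call(rbind, lapply(strsplit(keys, "/"), as.integer))
  expect_true(all(rowSums(cfg) == tab$n))
  # at rho = 0 no four-gamete configuration is ever observed
  fg <- cfg[, 1] > 0 & cfg[, 2] > 0 & cfg[, 3] > 0 & cfg[, 4] > 0
  expect_true(all(tab$loglik[fg, 1] == tab$floor_log))
  # probabilities normalize at every gridpoint (floor adds a small excess)
  for (g in c(1, 8, 15)) {
    p <- exp(tab$loglik[, g])
    expect_lt(abs(sum(p[tab$loglik[, g] > tab$floor_log]) - 1), 0.05)
  }
  # mean r2 across configurations decays with rho
  r2_of <- function(g) {
    p <- exp(tab$loglik[, g]); p[tab$loglik[, g] == tab$floor_log] <- 0
    r2 <- apply(cfg, 1, function(x) {
      n <- sum(x); pA <- (x[1] + x[2]) / n; pB <- (x[1] + x[3]) / n
      D <- x[1] / n - pA * pB
      D^2 / (pA * (1 - pA) * pB * (1 - pB))
    })
    sum(r2 * p) / sum(p)
  }
  r2m <- vapply(seq_along(tab$rho_grid), r2_of, numeric(1))
  expect_lte(cor(seq_along(r2m), r2m, method = "spearman"), 0)
  expect_error(build_two_locus_table(1), "n must be")
  expect_error(build_two_locus_table(5, rho_grid = c(1, 2)), "first point 0")
})

test_that("lookup canonicalization is symmetric in labels and loci", {
  tab <- local_table()
  # relabelling alleles or swapping loci never changes the likelihood
  expect_identical(mitorec:::.canonical_config(c(3, 2, 5, 2)),
                   mitorec:::.canonical_config(c(5, 2, 3, 2)))  # flip A
  expect_identical(mitorec:::.canonical_config(c(3, 2, 5, 2)),
                   mitorec:::.canonical_config(c(2, 3, 2, 5)))  # flip B
  expect_identical(mitorec:::.canonical_config(c(3, 2, 5, 2)),
                   mitorec:::.canonical_config(c(3, 5, 2, 2)))  # swap loci
})

test_that("table serialization round-trips", {
  tab <- local_table()
  f <- tempfile(fileext = ".tsv")
  write_lookup_table(tab, f)
  back <- read_lookup_table(f)
  expect_equal(back$rho_grid, tab$rho_grid)
  expect_equal(back$n, tab$n)
  expect_equal(unname(back$loglik), unname(tab$loglik), tolerance = 1e-6)
  expect_identical(rownames(back$loglik), rownames(tab$loglik))
})

test_that("constant rho sits at zero for tree-like data", {
  tab <- local_table()
  set.seed(51)
  a <- simulate_haplotypes(sim_params(12, 10000, 0.003, 0, seed = 13))
  s <- extract_biallelic_sites(a)
  est <- estimate_constant_rho(s, tab)
  expect_lte(est$rho_site, 1e-5)
  expect_true(est$n_pairs > 0)
})

test_that("doubling distances halves the constant-rho estimate", {
  tab <- local_table()
  set.seed(52)
  a <- simulate_haplotypes(sim_params(12, 8000, 0.003, 1e-3, seed = 14))
  s <- extract_biallelic_sites(a)
  s$circular <- FALSE
  est1 <- estimate_constant_rho(s, tab)
  s2 <- s
  s2$sites$pos <- s$sites$pos * 2L
  s2$alignment_length <- s$alignment_length * 2L
  est2 <- estimate_constant_rho(s2, tab)
  expect_gt(est1$rho_site, 0)
  expect_equal(est2$rho_site, est1$rho_site / 2, tolerance = 0.15)
})

test_that("r/m is reported against both Watterson theta and pi", {
  tab <- local_table()
  set.seed(53)
  a <- simulate_haplotypes(sim_params(12, 8000, 0.003, 1e-3, seed = 15))
  s <- extract_biallelic_sites(a)
  est <- estimate_constant_rho(s, tab)
  tw <- theta_watterson(s)
  expect_equal(est$r_over_m$rho_over_theta_w, est$rho_site / tw,
               tolerance = 1e-12)
  expect_true(is.finite(est$r_over_m$rho_over_pi))
})

test_that("variable-rho MCMC retains the documented number of samples", {
  tab <- local_table()
  set.seed(54)
  a <- simulate_haplotypes(sim_params(12, 6000, 0.003, 5e-4, seed = 16))
  s <- extract_biallelic_sites(a)
  m <- estimate_variable_rho(s, tab, n_iter = 4000, thin = 100,
                             burnin_fraction = 0.25, seed = 17)
  expect_identical(m$n_retained, as.integer(4000 * 0.75 / 100))
  expect_true(all(m$windows$ci_low <= m$windows$mean_rho + 1e-12, na.rm = TRUE))
  expect_true(all(m$windows$mean_rho <= m$windows$ci_high + 1e-12, na.rm = TRUE))
  expect_identical(unique(diff(m$windows$start)), 2000L)
})

test_that("variable-rho map stays low and flat on recombination-free data", {
  tab <- local_table()
  set.seed(55)
  a <- simulate_haplotypes(sim_params(12, 8000, 0.003, 0, seed = 18))
  s <- extract_biallelic_sites(a)
  m <- estimate_variable_rho(s, tab, n_iter = 10000, thin = 100, seed = 19)
  expect_lt(m$global_mean_rho, 0.003)  # well below theta
  expect_lt(mean(m$n_changepoints), n_sites(s) / 2)
})

test_that("variable-rho map ranks a planted hotspot correctly", {
  tab <- local_table()
  set.seed(56)
  wins <- 0L; tot <- 0L
  for (rep in 1:5) {
    hot <- simulate_haplotypes(sim_params(12, 6000, 0.004, 5e-3))
    cold <- simulate_haplotypes(sim_params(12, 6000, 0.004, 0))
    joint <- mt_alignment(cbind(unclass(hot), unclass(cold)),
                          sample_ids = rownames(hot), circular = FALSE)
    s <- extract_biallelic_sites(joint)
    m <- estimate_variable_rho(s, tab, n_iter = 8000, thin = 100, seed = rep)
    # windows adjacent to the concatenation junction are excluded: the two
    # halves have independent genealogies, which mimics a rate spike there
    left <- mean(m$windows$mean_rho[m$windows$end <= 4000], na.rm = TRUE)
    right <- mean(m$windows$mean_rho[m$windows$start >= 8000], na.rm = TRUE)
    tot <- tot + 1L
    if (is.finite(left) && is.finite(right) && left > right)
      wins <- wins + 1L
  }
  expect_gte(wins / tot, 0.8)
})
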