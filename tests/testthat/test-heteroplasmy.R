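# brute-force oracle: all circular windows of x, all-pairs Hamming vs all
# windows of y, with the gap-footprint rule applied on alignment columns
kmerlib_oracle <- function(gx, gy, k, min_diff) {
  chars_x <- strsplit(gx, "")[[1]]
  chars_y <- strsplit(gy, "")[[1]]
  gapcol <- chars_x == "-" | chars_y == "-"
  wins <- function(chars) {
    raw <- chars[chars != "-"]
    cols <- which(chars != "-")
    L <- length(raw)
    out <- character(0); foot_ok <- logical(0)
    for (i in seq_len(L)) {
      idx <- ((i - 1L):(i + k - 2L)) %% L + 1L
      out <- c(out, paste(raw[idx], collapse = ""))
      c1 <- cols[i]; c2 <- cols[idx[k]]
      span <- if (c1 <= c2 && i + k - 1L <= L) c1:c2 else
        c(c1:length(chars), 1:c2)
      foot_ok <- c(foot_ok, !any(gapcol[span]))
    }
    list(kmers = out, ok = foot_ok)
  }
  wx <- wins(chars_x); wy <- wins(chars_y)
  xk <- unique(wx$kmers[wx$ok])
  yk <- wy$kmers[wy$ok]
  keep <- vapply(xk, function(x) {
    all(vapply(yk, function(y)
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]) >= min_diff,
      logical(1)))
  }, logical(1))
  sort(xk[keep])
}

test_that("k-mer library equals exhaustive enumeration on a circular toy", {
  set.seed(61)
  gx <- rand_seq(60)
  gy <- mutate_at(gx, c(10, 30, 50))  # 3 well-spaced SNPs
  aln <- mt_alignment(c(gx, gy), sample_ids = c("x", "y"), circular = TRUE)
  lib <- build_kmer_library(aln, "x", "y", k = 20, min_diff = 2)
  expect_identical(lib$kmers, kmerlib_oracle(gx, gy, 20, 2))
  expect_identical(lib$size, length(lib$kmers))
  # identical types -> empty library
  aln2 <- mt_alignment(c(gx, gx), sample_ids = c("x", "y"), circular = TRUE)
  expect_identical(build_kmer_library(aln2, "x", "y", k = 20)$size, 0L)
  expect_error(build_kmer_library(aln, "x", "y", k = 100), "parameter error")
})

test_that("k-mers spanning alignment gaps are excluded", {
  set.seed(62)
  base <- rand_seq(60)
  # y has a deletion (gap run) enclosing a SNP region
  gx <- base
  gy <- paste0(substr(mutate_at(base, c(28, 29)), 1, 24), "------",
               substr(base, 31, 60))
  aln <- mt_alignment(c(gx, gy), sample_ids = c("x", "y"), circular = TRUE)
  lib <- build_kmer_library(aln, "x", "y", k = 15, min_diff = 1)
  expect_identical(lib$kmers, kmerlib_oracle(gx, gy, 15, 1))
  # no kept x k-mer covers the gap columns 25..30 (0-based 24..29)
  gap_sub <- substr(gx, 25, 30)
  expect_false(any(grepl(gap_sub, lib$kmers, fixed = TRUE)))
})

test_that("heteroplasmy estimates honour the defining identities", {
  set.seed(63)
  L <- 1500
  base <- rand_seq(L)
  t_m <- base
  t_a <- mutate_at(base, c(200, 240, 800, 840))
  t_b <- mutate_at(base, c(500, 540, 1100, 1140))
  aln <- mt_alignment(c(t_m, t_a, t_b), sample_ids = c("M", "A", "B"),
                      circular = TRUE)
  libs <- build_all_kmer_libraries(aln, k = 151, min_diff = 2)
  # all reads from major -> H_i = 0 for every candidate
  rs <- simulate_mixture_reads(t_m, t_a, 0, 100, 151, 0, seed = 1)
  est <- estimate_heteroplasmy(rs, "M", c("A", "B"), libs)
  expect_equal(est$H_hat, 0)
  # symmetric rates -> H = 0.5: an exact 50/50 error-free mixture
  rs2 <- simulate_mixture_reads(t_m, t_a, 0.5, 300, 151, 0, seed = 2)
  est2 <- estimate_heteroplasmy(rs2, "M", c("A", "B"), libs)
  expect_equal(est2$selected_candidate, "A")
  expect_equal(est2$H_hat, 0.5, tolerance = 0.1)
  # reads of the wrong length are excluded and counted
  est3 <- estimate_heteroplasmy(c(rs$reads, "ACGT"), "M", c("A", "B"), libs)
  expect_identical(est3$n_reads_excluded, 1L)
  # empty candidate library -> candidate skipped with reason
  libs2 <- libs
  libs2[["A|M"]]$kmers <- character(0)
  libs2[["A|M"]]$size <- 0L
  est4 <- estimate_heteroplasmy(rs2, "M", c("A", "B"), libs2)
  expect_true(est4$per_candidate$skipped[est4$per_candidate$candidate == "A"])
  libs2[["B|M"]]$size <- 0L
  expect_error(estimate_heteroplasmy(rs2, "M", c("A"), libs2), "skipped")
})

test_that("swapping major and minor roles reflects H about one half", {
  set.seed(64)
  L <- 1500
  base <- rand_seq(L)
  t_m <- base
  t_a <- mutate_at(base, c(200, 240, 800, 840, 1200, 1240))
  aln <- mt_alignment(c(t_m, t_a), sample_ids = c("M", "A"), circular = TRUE)
  libs <- build_all_kmer_libraries(aln, k = 151, min_diff = 2)
  rs <- simulate_mixture_reads(t_m, t_a, 0.2, 400, 151, 0.001, seed = 3)
  h1 <- estimate_heteroplasmy(rs, "M", "A", libs)$H_hat
  h2 <- estimate_heteroplasmy(rs, "A", "M", libs)$H_hat
  expect_equal(h2, 1 - h1, tolerance = 0.05)
})

test_that("H is monotone in the planted minor fraction", {
  set.seed(65)
  L <- 1500
  base <- rand_seq(L)
  t_m <- base
  t_a <- mutate_at(base, c(200, 240, 800, 840))
  aln <- mt_alignment(c(t_m, t_a), sample_ids = c("M", "A"), circular = TRUE)
  libs <- build_all_kmer_libraries(aln, k = 151, min_diff = 2)
  hs <- vapply(c(0, 0.01, 0.05, 0.2), function(f) {
    rs <- simulate_mixture_reads(t_m, t_a, f, 400, 151, 0.001, seed = 66)
    estimate_heteroplasmy(rs, "M", "A", libs)$H_hat
  }, numeric(1))
  expect_true(all(diff(hs) >= 0))
})

test_that("beta outlier detection flags a planted extreme", {
  # note: with rho = 1 even the true model flags the bulk maximum with
  # probability ~P(N(1-F(Y_max)) < 1) ~ 0.6, so "exactly one outlier" can
  # never hold in ~95% of replicates; the planted value itself must always
  # be caught and the spurious flags stay confined to the top order
  # statistics
  set.seed(67)
  hits <- 0L; n_extra <- integer(0)
  for (rep in 1:50) {
    vals <- c(rbeta(99, 0.5, 99.5), 0.5)   # bulk mean ~0.005 + one outlier
    out <- beta_outlier_detection(vals, rho = 1)
    if (out$outlier[100]) hits <- hits + 1L
    n_extra <- c(n_extra, sum(out$outlier) - 1L)
  }
  expect_gte(hits, 48L)  # >= 95% of seeded replicates catch the plant
  expect_lte(median(n_extra), 1)
  expect_lte(max(n_extra), 5L)
  # constant input -> degenerate, nothing flagged
  cst <- beta_outlier_detection(rep(0.2, 10))
  expect_true(cst$degenerate)
  expect_false(any(cst$outlier))
  # rho = N disables flagging
  v <- rbeta(20, 1, 50)
  expect_false(any(beta_outlier_detection(v, rho = 20)$outlier))
  expect_error(beta_outlier_detection(c(0.1, 1.2, 0.3, 0.4, 0.5)), "values")
  expect_error(beta_outlier_detection(c(0.1, 0.2)), ">= 5")
})

test_that("Mann-Whitney matches exhaustive enumeration and wilcox.test", {
  r <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_identical(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)  # 2/20 rank assignments as extreme
  # identical groups -> p = 1 exactly
  r2 <- mann_whitney_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p_value, 1)
  # cross-check exact path against base R on untied data
  set.seed(68)
  for (rep in 1:5) {
    a <- sample(100, 5); b <- sample(200, 6)
    while (any(a %in% b)) b <- sample(200, 6)
    ours <- mann_whitney_test(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
  # large-sample normal path has power for a 2 SD shift
  set.seed(69)
  rej <- mean(replicate(100, {
    mann_whitney_test(rnorm(30), rnorm(30, 2))$p_value < 0.05
  }))
  expect_gte(rej, 0.9)
  expect_error(mann_whitney_test(numeric(0), 1), "non-empty")
})
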