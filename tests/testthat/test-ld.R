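test_that("ld_statistics matches hand-enumerated values", {
  g <- geno_from_counts(4, 1, 1, 4)
  st <- ld_statistics(g$a, g$b)
  expect_equal(st$D, 0.15)
  expect_equal(st$D_prime, 0.6)
  expect_equal(st$r2, 0.36)
  expect_true(st$four_gametes)
  # complete LD
  g2 <- geno_from_counts(5, 0, 0, 5)
  st2 <- ld_statistics(g2$a, g2$b)
  expect_equal(st2$r2, 1); expect_equal(st2$D_prime, 1)
  expect_false(st2$four_gametes)
  # exact independence
  g3 <- geno_from_counts(1, 1, 1, 1)
  st3 <- ld_statistics(g3$a, g3$b)
  expect_equal(st3$D, 0); expect_equal(st3$r2, 0)
  # monomorphic site -> flagged unusable
  st4 <- ld_statistics(c(1L, 1L, 1L), c(0L, 1L, 0L))
  expect_false(st4$usable)
  expect_true(is.na(st4$r2))
})

test_that("LD statistics agree with enumeration on all small count tables", {
  for (n11 in 0:2) for (n10 in 0:2) for (n01 in 0:2) for (n00 in 0:2) {
    if ((n11 + n10) == 0 || (n01 + n00) == 0) next   # monomorphic site a
    if ((n11 + n01) == 0 || (n10 + n00) == 0) next   # monomorphic site b
    g <- geno_from_counts(n11, n10, n01, n00)
    st <- ld_statistics(g$a, g$b)
    o <- ld_oracle(n11, n10, n01, n00)
    expect_equal(st$D, o$D, tolerance = 1e-12)
    expect_equal(st$D_prime, o$Dp, tolerance = 1e-12)
    expect_equal(st$r2, o$r2, tolerance = 1e-12)
    expect_identical(st$four_gametes, o$fg)
    expect_true(st$r2 >= 0 && st$r2 <= 1 + 1e-12)
    expect_true(st$D_prime >= 0 && st$D_prime <= 1 + 1e-12)
  }
})

test_that("four_gamete_scan counts violating pairs over shared samples", {
  # haplotypes {AC, AT, GC, GT} at two sites -> violation
  a <- aln_from_patterns(rbind(c(1, 1, 0, 0), c(1, 0, 1, 0)), c(3, 8), 12)
  s <- extract_biallelic_sites(a)
  fg <- four_gamete_scan(s)
  expect_identical(fg$n_violating, 1L)
  expect_true(fg$pairs$four_gametes[1])
  # nested sites {AC, AT, GT} -> no violation
  b <- aln_from_patterns(rbind(c(1, 1, 0), c(1, 0, 0)), c(3, 8), 12)
  fgb <- four_gamete_scan(extract_biallelic_sites(b))
  expect_identical(fgb$n_violating, 0L)
})

test_that("four-gamete counts are invariant to sample order and allele labels", {
  set.seed(41)
  a <- simulate_haplotypes(sim_params(10, 6000, 0.003, 2e-3, seed = 6))
  s <- extract_biallelic_sites(a)
  n0 <- four_gamete_scan(s, return_pairs = FALSE)$n_violating
  # permute samples
  perm <- sample(nrow(a))
  a2 <- mt_alignment(unclass(a)[perm, ], sample_ids = rownames(a)[perm],
                     circular = TRUE)
  expect_identical(
    four_gamete_scan(extract_biallelic_sites(a2), return_pairs = FALSE)$n_violating,
    n0)
  # relabel alleles: flip the genotype coding at every site
  s3 <- s
  s3$geno <- 1L - s3$geno
  expect_identical(four_gamete_scan(s3, return_pairs = FALSE)$n_violating, n0)
})

test_that("haplotype_blocks tiles sites and matches the DP oracle", {
  # no violations anywhere -> one block
  a <- aln_from_patterns(rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 0)),
                         c(2, 5, 9), 12)
  s <- extract_biallelic_sites(a)
  s$circular <- FALSE
  bl <- haplotype_blocks(s)
  expect_identical(nrow(bl), 1L)
  expect_identical(bl$n_sites, 3L)

  # single violating pair between consecutive sites -> exactly 2 blocks
  b <- aln_from_patterns(rbind(c(1, 1, 0, 0), c(1, 0, 1, 0)), c(2, 9), 12)
  sb <- extract_biallelic_sites(b)
  sb$circular <- FALSE
  blb <- haplotype_blocks(sb)
  expect_identical(nrow(blb), 2L)

  # planted mosaic: left panel pattern vs right panel pattern
  set.seed(42)
  left <- matrix(rep(c(1, 1, 1, 0, 0, 0), 15), 15, byrow = TRUE)
  right <- matrix(rep(c(1, 0, 0, 1, 0, 0), 15), 15, byrow = TRUE)
  pat <- rbind(left, right)
  al <- aln_from_patterns(pat, seq(5, 5 + 29 * 10, 10), 400)
  sal <- extract_biallelic_sites(al)
  sal$circular <- FALSE
  blal <- haplotype_blocks(sal)
  expect_identical(nrow(blal), 2L)
  expect_true(abs(blal$site_to[1] - 15L) <= 1L)
  # DP oracle agrees on the minimal block count
  expect_identical(nrow(blal), as.integer(min_blocks_oracle(sal$geno)))

  # every site belongs to exactly one block
  covered <- unlist(lapply(seq_len(nrow(blal)), function(i)
    blal$site_from[i]:blal$site_to[i]))
  expect_setequal(covered, seq_len(n_sites(sal)))

  # random mosaics vs DP oracle
  for (rep in 1:5) {
    pat2 <- matrix(sample(0:1, 8 * 12, TRUE), 12, 8)
    keep <- apply(pat2, 1, function(x) length(unique(x)) == 2L)
    pat2 <- pat2[keep, , drop = FALSE]
    if (nrow(pat2) < 2) next
    a2 <- aln_from_patterns(pat2, seq(3, 3 + (nrow(pat2) - 1) * 7, 7), 200)
    s2 <- extract_biallelic_sites(a2)
    s2$circular <- FALSE
    expect_identical(nrow(haplotype_blocks(s2)),
                     as.integer(min_blocks_oracle(s2$geno)))
  }
})

test_that("circular data can merge the terminal and initial blocks", {
  # violation only between middle sites; first and last compatible
  pat <- rbind(c(1, 1, 0, 0),   # site 1 (compatible with site 3)
               c(1, 0, 1, 0),   # violates site 1
               c(1, 1, 0, 0))   # violates site 2, compatible with site 1
  a <- aln_from_patterns(pat, c(2, 50, 95), 100, circular = TRUE)
  s <- extract_biallelic_sites(a)
  bl <- haplotype_blocks(s)
  expect_identical(nrow(bl), 2L)
  expect_true(any(bl$site_to < bl$site_from))  # the wrapped block
})
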