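test_that("load_alignment enforces the FASTA contract", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">a", "acgtacgtac", ">b", "ACGTACGTAC", ">c", "ACGTACGTAC"), f)
  aln <- load_alignment(f, circular = FALSE)
  expect_s3_class(aln, "mt_alignment")
  expect_identical(dim(unclass(aln)), c(3L, 10L))
  expect_identical(unname(alignment_strings(aln)[1]), "ACGTACGTAC")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), f)
  expect_error(load_alignment(f), "format error")
  writeLines(character(0), f)
  expect_error(load_alignment(f), "format error")
  # U -> T
  writeLines(c(">a", "ACGU", ">b", "ACGU"), f)
  expect_identical(unname(alignment_strings(load_alignment(f))[1]), "ACGT")
})

test_that("rotate_to_reference recovers rotations and strand flips", {
  set.seed(21)
  ref <- rand_seq(2000)
  expect_identical(rotate_to_reference(ref, ref, 300), ref)
  rot <- paste0(substr(ref, 1001, 2000), substr(ref, 1, 1000))
  expect_identical(rotate_to_reference(rot, ref, 300), ref)
  rc <- reverse_complement(paste0(substr(ref, 501, 2000), substr(ref, 1, 500)))
  expect_identical(rotate_to_reference(rc, ref, 300), ref)
  # near-match fallback: one mismatch inside the anchor
  rot2 <- mutate_at(rot, 1100)  # inside the anchor after rotation
  out <- rotate_to_reference(rot2, ref, 300)
  expect_identical(substr(out, 400, 2000), substr(ref, 400, 2000))
  expect_error(rotate_to_reference(rand_seq(2000), ref, 300), "rotation error")
})

test_that("collapse_mitotypes masks repeat-adjacent and gappy columns", {
  # identical rows -> one mitotype
  a <- mt_alignment(c("ACGTACGT", "ACGTACGT", "ACGTACGT"), circular = FALSE)
  mts <- collapse_mitotypes(a)
  expect_length(mts$mitotypes, 1L)
  expect_setequal(mts$mitotypes[[1]]$member_sample_ids, rownames(a))

  # SNP flanking a 7-bp poly-C run is masked -> sequences merge
  s1 <- paste0("ATGTG", strrep("C", 7), "AGTACGTAGCTAAA")
  s2 <- sub("AGTACG", "GGTACG", s1)  # SNP at the column after the run
  m2 <- collapse_mitotypes(mt_alignment(c(s1, s2), circular = FALSE),
                           homopolymer_min = 5)
  expect_length(m2$mitotypes, 1L)

  # a clean SNP far from any repeat separates mitotypes
  s3 <- "ATGCATGCATGCATGCATGC"
  s4 <- mutate_at(s3, 10)
  m3 <- collapse_mitotypes(mt_alignment(c(s3, s4), circular = FALSE))
  expect_length(m3$mitotypes, 2L)

  # gappy window masking: SNP inside a gap-rich region is ignored
  g1 <- paste0("ATGCATGCA", "--A--T--G", "ATGCATGCATGC")
  g2 <- paste0("ATGCATGCA", "--A--A--G", "ATGCATGCATGC")
  m4 <- collapse_mitotypes(mt_alignment(c(g1, g2), circular = FALSE),
                           gappy_window = 9, gappy_fraction = 0.2)
  expect_length(m4$mitotypes, 1L)
})

test_that("collapse_mitotypes is idempotent and partitions samples", {
  set.seed(22)
  a <- simulate_haplotypes(sim_params(10, 3000, 0.002, 0, seed = 8))
  mts <- collapse_mitotypes(a)
  members <- unlist(lapply(mts$mitotypes, `[[`, "member_sample_ids"))
  expect_setequal(members, rownames(a))
  expect_identical(anyDuplicated(members), 0L)
  reps <- mitotype_alignment(mts)
  mts2 <- collapse_mitotypes(reps)
  expect_length(mts2$mitotypes, length(mts$mitotypes))
})

test_that("extract_biallelic_sites matches an exhaustive column scan", {
  a <- mt_alignment(c("AAGACGTA", "AAGTCGTC", "ATGACGTA", "ATGTC-TC"),
                    circular = FALSE)
  s <- extract_biallelic_sites(a)
  # brute force over columns
  m <- unclass(a)
  expected <- integer(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j][m[, j] %in% c("A", "C", "G", "T")]
    if (length(unique(col)) == 2L) expected <- c(expected, j - 1L)
  }
  expect_identical(s$sites$pos, expected)
  # triallelic columns are excluded
  tri <- mt_alignment(c("AAA", "GAA", "TAA"), circular = FALSE)
  expect_identical(n_sites(extract_biallelic_sites(tri)), 0L)
  # invariant alignment -> empty table
  inv <- mt_alignment(c("ACGT", "ACGT"), circular = FALSE)
  expect_identical(n_sites(extract_biallelic_sites(inv)), 0L)
  # gap/N recorded as missing, not as alleles
  g <- mt_alignment(c("ANT", "A-T", "AGT", "ACT"), circular = FALSE)
  sg <- extract_biallelic_sites(g)
  expect_identical(n_sites(sg), 1L)
  expect_identical(sum(is.na(sg$geno[, 1])), 2L)
  # min_minor_count filter
  s2 <- extract_biallelic_sites(a, min_minor_count = 2L)
  expect_true(all(s2$sites$minor_count >= 2L))
})

test_that("site extraction is invariant to row order", {
  set.seed(23)
  a <- simulate_haplotypes(sim_params(8, 2000, 0.005, 0, seed = 4))
  s1 <- extract_biallelic_sites(a)
  perm <- sample(nrow(a))
  a2 <- mt_alignment(unclass(a)[perm, ], sample_ids = rownames(a)[perm],
                     circular = TRUE)
  s2 <- extract_biallelic_sites(a2)
  expect_identical(s1$sites, s2$sites)
})

test_that("haplotype_network equals a minimum spanning tree", {
  # 2 mitotypes at distance 5
  base <- strrep("ACGT", 10)
  m <- collapse_mitotypes(mt_alignment(c(base, mutate_at(base, c(1, 5, 9, 13, 17))),
                                       circular = FALSE))
  net <- haplotype_network(m)
  expect_identical(nrow(net), 1L)
  expect_identical(net$n_differences, 5L)

  # distances 1,1,2: MST keeps the two weight-1 edges
  t1 <- base
  t2 <- mutate_at(base, 2)
  t3 <- mutate_at(base, 30)
  m3 <- collapse_mitotypes(mt_alignment(c(t1, t2, t3), circular = FALSE))
  net3 <- haplotype_network(m3)
  expect_identical(sort(net3$n_differences), c(1L, 1L))

  # random 6-mitotype set: total weight equals igraph MST weight
  skip_if_not_installed("igraph")
  set.seed(24)
  seqs <- rand_seq(60)
  types <- c(seqs, vapply(1:5, function(i)
    mutate_at(seqs, sample(60, i * 2)), character(1)))
  mm <- collapse_mitotypes(mt_alignment(types, circular = FALSE))
  net6 <- haplotype_network(mm)
  k <- length(mm$mitotypes)
  dm <- matrix(0, k, k)
  sm <- do.call(rbind, strsplit(vapply(mm$mitotypes, `[[`, character(1),
                                       "representative"), ""))
  if (length(mm$masked_columns))
    sm <- sm[, -(mm$masked_columns + 1L), drop = FALSE]
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    dm[i, j] <- dm[j, i] <- sum(sm[i, ] != sm[j, ])
  g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                           weighted = TRUE)
  mst_w <- sum(igraph::E(igraph::mst(g))$weight)
  # the network must connect all mitotypes and contain a full MST: an MST
  # restricted to the network's edges reaches the same total weight
  expect_gte(nrow(net6), k - 1L)
  ids <- vapply(mm$mitotypes, `[[`, character(1), "id")
  sub <- igraph::graph_from_data_frame(
    data.frame(from = net6$from_mitotype, to = net6$to_mitotype,
               weight = net6$n_differences),
    directed = FALSE, vertices = ids)
  expect_true(igraph::is_connected(sub))
  expect_equal(sum(igraph::E(igraph::mst(sub))$weight), mst_w)
})
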