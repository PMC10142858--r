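# shared fixture builders; all randomness is seeded by the caller

rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                              collapse = "")

# deterministic base substitution (A->C->G->T->A) at 1-based positions
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  ch[pos] <- rot[ch[pos]]
  paste(ch, collapse = "")
}

# alignment from genotype patterns: `patterns` is a sites x samples 0/1
# matrix; site j is placed at column positions[j] of an otherwise constant
# sequence (A background, minor allele G)
aln_from_patterns <- function(patterns, positions, L, circular = FALSE) {
  n <- ncol(patterns)
  m <- matrix("A", n, L)
  for (j in seq_len(nrow(patterns)))
    m[patterns[j, ] == 1L, positions[j]] <- "G"
  mt_alignment(m, sample_ids = sprintf("s%02d", seq_len(n)),
               circular = circular)
}

# independent minimal-segmentation oracle: DP over ordered sites, where a
# segment is feasible iff no pair inside it shows all four gametes
min_blocks_oracle <- function(geno) {
  S <- ncol(geno)
  viol <- function(i, j) {
    a <- geno[, i]; b <- geno[, j]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    all(c(any(a & b), any(a & !b), any(!a & b), any(!a & !b)))
  }
  feasible <- matrix(TRUE, S, S)
  for (i in seq_len(S - 1L)) for (j in (i + 1L):S) {
    bad <- FALSE
    for (x in i:(j - 1L)) for (y in (x + 1L):j) if (viol(x, y)) bad <- TRUE
    feasible[i, j] <- !bad
  }
  best <- rep(Inf, S + 1L)
  best[1L] <- 0
  for (j in seq_len(S))
    for (i in seq_len(j))
      if (feasible[i, j]) best[j + 1L] <- min(best[j + 1L], best[i] + 1)
  best[S + 1L]
}
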