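# Independent oracles used by both module and acceptance tests.  These are
# written from first principles (definitions and exhaustive enumeration),
# never from the package internals.

# modified Nei-Gojobori per-codon oracle: weighted site counts and
# path-averaged synonymous/nonsynonymous differences
ng_oracle <- function(c1, c2, tstv = 2, code = "standard") {
  gc <- Biostrings::GENETIC_CODE
  if (code == "mold_mito") gc[["TGA"]] <- "W"
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  syn_sites <- function(cod) {
    ch <- strsplit(cod, "")[[1]]
    s <- 0
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      mut <- ch; mut[p] <- b
      w <- if (b == ts[[ch[p]]]) tstv else 1
      if (gc[[paste(mut, collapse = "")]] == gc[[cod]]) s <- s + w / (tstv + 2)
    }
    s
  }
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  dpos <- which(ch1 != ch2)
  perms <- list(dpos)
  if (length(dpos) == 2) perms <- list(dpos, rev(dpos))
  if (length(dpos) == 3) {
    p <- dpos
    perms <- list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)], p[c(2, 3, 1)],
                  p[c(3, 1, 2)], p[c(3, 2, 1)])
  }
  res <- NULL
  for (ord in perms) {
    cur <- ch1; sd <- 0; nd <- 0; stop_hit <- FALSE
    for (p in ord) {
      prev <- paste(cur, collapse = "")
      cur[p] <- ch2[p]
      nxt <- paste(cur, collapse = "")
      if (gc[[nxt]] == "*" && nxt != c2) stop_hit <- TRUE
      if (gc[[nxt]] == gc[[prev]] && gc[[nxt]] != "*") sd <- sd + 1 else
        nd <- nd + 1
    }
    res <- rbind(res, c(sd, nd, stop_hit))
  }
  ok <- res[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(res))
  list(S = (syn_sites(c1) + syn_sites(c2)) / 2,
       sd = mean(res[ok, 1]), nd = mean(res[ok, 2]))
}

# direct 2x2 enumeration oracle for D, D', r2 from haplotype counts
ld_oracle <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / n; pB <- (n11 + n01) / n
  D <- n11 / n - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, Dp = if (Dmax > 0) abs(D) / Dmax else 0,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       fg = n11 > 0 && n10 > 0 && n01 > 0 && n00 > 0)
}

geno_from_counts <- function(n11, n10, n01, n00) {
  a <- c(rep(1L, n11), rep(1L, n10), rep(0L, n01), rep(0L, n00))
  b <- c(rep(1L, n11), rep(0L, n10), rep(1L, n01), rep(0L, n00))
  list(a = a, b = b)
}
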