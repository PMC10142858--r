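#' Linkage disequilibrium statistics for a pair of biallelic sites
#'
#' For a pair of sites with minor-allele indicators `ga`, `gb` (0/1/NA; NA
#' samples are dropped pairwise): with haplotype frequency `p_AB` and allele
#' frequencies `p_A`, `p_B`, computes `D = p_AB - p_A p_B`, `D' = |D| /
#' D_max` where `D_max = min(p_A (1-p_B), (1-p_A) p_B)` for `D > 0` and
#' `min(p_A p_B, (1-p_A)(1-p_B))` otherwise, and `r^2 = D^2 / (p_A (1-p_A)
#' p_B (1-p_B))`. The four-gamete flag is TRUE iff all four haplotypes are
#' observed.
#'
#' @param ga,gb Integer vectors of 0/1/NA over the same samples.
#' @return List with `D`, `D_prime`, `r2`, `four_gametes`, `n` (complete
#'   cases) and `usable` (FALSE when a site is monomorphic among shared
#'   samples, in which case the statistics are NA).
#' @export
ld_statistics <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  a <- ga[ok]; b <- gb[ok]
  n <- length(a)
  out <- list(D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
              four_gametes = NA, n = n, usable = FALSE)
  if (n == 0L || length(unique(a)) < 2L || length(unique(b)) < 2L) return(out)
  pA <- mean(a); pB <- mean(b)
  pAB <- mean(a == 1L & b == 1L)
  D <- pAB - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  out$D <- D
  out$D_prime <- if (Dmax > 0) abs(D) / Dmax else 0
  out$r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  n11 <- sum(a == 1L & b == 1L); n10 <- sum(a == 1L & b == 0L)
  n01 <- sum(a == 0L & b == 1L); n00 <- sum(a == 0L & b == 0L)
  out$four_gametes <- n11 > 0L && n10 > 0L && n01 > 0L && n00 > 0L
  out$usable <- TRUE
  out
}

# Pairwise haplotype-class counts via cross-products; NA-safe.  Returns a
# list of SxS matrices n11, n10, n01, n00 and `complete` (pairwise n).
.pair_counts <- function(geno) {
  G1 <- geno; G1[is.na(G1)] <- 0L
  P <- !is.na(geno) * 1L
  G0 <- P - G1
  list(n11 = crossprod(G1, G1), n10 = crossprod(G1, G0),
       n01 = crossprod(G0, G1), n00 = crossprod(G0, G0),
       complete = crossprod(P, P))
}

#' Scan all site pairs for four-gamete violations
#'
#' Evaluates every unordered pair of biallelic sites over the samples
#' non-missing at both sites. Observing all four haplotypes at a pair is
#' incompatible with a single genealogy under infinite sites and therefore
#' evidence of recombination (or recurrent mutation).
#'
#' @param sites An `mt_sites` with >= 2 sites.
#' @param return_pairs If TRUE (default), a per-pair table with LD
#'   statistics is returned; set FALSE for large scans where only counts
#'   are needed.
#' @return List with `n_violating`, `n_pairs` (pairs where both sites are
#'   biallelic among shared samples), and `pairs` (data.frame with
#'   `site_a`, `site_b` indices, positions, `distance`, `D`, `D_prime`,
#'   `r2`, `four_gametes`; NULL when `return_pairs = FALSE`).
#' @export
four_gamete_scan <- function(sites, return_pairs = TRUE) {
  stopifnot(inherits(sites, "mt_sites"))
  S <- n_sites(sites)
  if (S < 2L) return(list(n_violating = 0L, n_pairs = 0L, pairs = NULL))
  pc <- .pair_counts(sites$geno)
  biall <- (pc$n11 + pc$n10) > 0 & (pc$n01 + pc$n00) > 0 &
    (pc$n11 + pc$n01) > 0 & (pc$n10 + pc$n00) > 0
  viol <- pc$n11 > 0 & pc$n10 > 0 & pc$n01 > 0 & pc$n00 > 0
  ut <- upper.tri(viol)
  n_pairs <- sum(biall[ut])
  n_violating <- sum(viol[ut] & biall[ut])
  pairs <- NULL
  if (return_pairs) {
    idx <- which(ut & biall, arr.ind = TRUE)
    if (nrow(idx)) {
      pos <- sites$sites$pos
      d <- abs(pos[idx[, 2L]] - pos[idx[, 1L]])
      if (isTRUE(sites$circular))
        d <- pmin(d, sites$alignment_length - d)
      stats <- lapply(seq_len(nrow(idx)), function(r)
        ld_statistics(sites$geno[, idx[r, 1L]], sites$geno[, idx[r, 2L]]))
      pairs <- data.frame(site_a = idx[, 1L], site_b = idx[, 2L],
                          pos_a = pos[idx[, 1L]], pos_b = pos[idx[, 2L]],
                          distance = d,
                          D = vapply(stats, `[[`, numeric(1), "D"),
                          D_prime = vapply(stats, `[[`, numeric(1), "D_prime"),
                          r2 = vapply(stats, `[[`, numeric(1), "r2"),
                          four_gametes = vapply(stats, `[[`, logical(1),
                                                "four_gametes"))
    }
  }
  list(n_violating = n_violating, n_pairs = n_pairs, pairs = pairs)
}

#' Haplotype blocks from the four-gamete condition
#'
#' Segments the ordered biallelic sites into maximal blocks by greedy
#' left-to-right extension: a block grows while every site pair inside it
#' shows at most three haplotypes; a site introducing a fourth haplotype
#' with any block member closes the block and starts the next one. On
#' circular data the final and first blocks are merged when their union is
#' violation-free (such a block wraps the origin).
#'
#' @param sites An `mt_sites` with >= 1 site.
#' @return A data.frame with 0-based half-open `start_column`,
#'   `end_column` (start > end marks a block wrapping the origin),
#'   `n_sites`, and `site_from`, `site_to` (1-based site indices;
#'   `site_to < site_from` for the wrapped block).
#' @export
haplotype_blocks <- function(sites) {
  stopifnot(inherits(sites, "mt_sites"), n_sites(sites) >= 1L)
  S <- n_sites(sites)
  pos <- sites$sites$pos
  if (S == 1L)
    return(data.frame(start_column = pos[1L], end_column = pos[1L] + 1L,
                      n_sites = 1L, site_from = 1L, site_to = 1L))
  pc <- .pair_counts(sites$geno)
  viol <- pc$n11 > 0 & pc$n10 > 0 & pc$n01 > 0 & pc$n00 > 0
  blocks <- list()
  cur <- 1L
  for (s in 2:S) {
    if (any(viol[cur:(s - 1L), s])) {
      blocks[[length(blocks) + 1L]] <- c(cur, s - 1L)
      cur <- s
    }
  }
  blocks[[length(blocks) + 1L]] <- c(cur, S)
  wrapped <- FALSE
  if (isTRUE(sites$circular) && length(blocks) > 1L) {
    first <- blocks[[1L]]; last <- blocks[[length(blocks)]]
    cross <- viol[last[1L]:last[2L], first[1L]:first[2L], drop = FALSE]
    if (!any(cross)) {
      blocks[[1L]] <- c(last[1L], first[2L])
      blocks[[length(blocks)]] <- NULL
      wrapped <- TRUE
    }
  }
  out <- data.frame(start_column = integer(0), end_column = integer(0),
                    n_sites = integer(0), site_from = integer(0),
                    site_to = integer(0))
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    if (b == 1L && wrapped) {
      out <- rbind(out, data.frame(start_column = pos[bl[1L]],
                                   end_column = pos[bl[2L]] + 1L,
                                   n_sites = (S - bl[1L] + 1L) + bl[2L],
                                   site_from = bl[1L], site_to = bl[2L]))
    } else {
      out <- rbind(out, data.frame(start_column = pos[bl[1L]],
                                   end_column = pos[bl[2L]] + 1L,
                                   n_sites = bl[2L] - bl[1L] + 1L,
                                   site_from = bl[1L], site_to = bl[2L]))
    }
  }
  out
}
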