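# permutation p-values use the add-one estimator so p is never 0
.perm_p <- function(perm_stats, observed, side = c("ge", "le")) {
  side <- match.arg(side)
  hits <- if (side == "ge") sum(perm_stats >= observed) else
    sum(perm_stats <= observed)
  (1 + hits) / (1 + length(perm_stats))
}

.mt_test <- function(statistic, p_value, n_permutations, method, ...) {
  structure(c(list(statistic = statistic, p_value = p_value,
                   n_permutations = n_permutations, method = method),
              list(...)), class = "mt_test")
}

#' @export
print.mt_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Mantel tests of linkage disequilibrium decay with distance
#'
#' Cuts the (circular) alignment into consecutive linear chunks of
#' `chunk_size` columns, and within each chunk correlates pairwise LD
#' (`r^2` or `D'`) between segregating sites with the physical distance
#' between them (Mantel test, permuting site labels). Recombination predicts
#' LD decay with distance, so the default alternative is a one-sided test
#' for negative correlation.
#'
#' @param aln An [mt_alignment].
#' @param chunk_size Chunk width in alignment columns.
#' @param stat `"r2"` or `"Dprime"`.
#' @param min_minor_count Minimum minor-allele count for a site.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @param offset 0-based column at which chunking starts (sensitivity
#'   analysis for arbitrary chunk boundaries).
#' @param alternative `"negative"` (one-sided, default) or `"two.sided"`.
#' @return A data.frame with one row per chunk: `chunk`, `start`, `end`,
#'   `n_sites`, `statistic` (Mantel r), `p_value`, `n_perm`, `testable`.
#'   Chunks with fewer than 3 segregating sites are reported untestable.
#' @export
ld_distance_mantel <- function(aln, chunk_size, stat = c("r2", "Dprime"),
                               min_minor_count = 1L, n_perm = 999L,
                               seed = NULL, offset = 0L,
                               alternative = c("negative", "two.sided")) {
  stopifnot(inherits(aln, "mt_alignment"))
  stat <- match.arg(stat)
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(aln)
  if (chunk_size > L) stop("chunk_size exceeds alignment length")
  n_chunk <- L %/% chunk_size
  out <- data.frame(chunk = seq_len(n_chunk), start = NA_integer_,
                    end = NA_integer_, n_sites = 0L, statistic = NA_real_,
                    p_value = NA_real_, n_perm = n_perm, testable = FALSE)
  m <- unclass(aln)
  for (ck in seq_len(n_chunk)) {
    cols0 <- (offset + (ck - 1L) * chunk_size + 0:(chunk_size - 1L)) %% L
    out$start[ck] <- cols0[1L]
    out$end[ck] <- cols0[length(cols0)] + 1L
    sub <- mt_alignment(m[, cols0 + 1L, drop = FALSE],
                        sample_ids = rownames(m), circular = FALSE)
    sites <- extract_biallelic_sites(sub, min_minor_count = min_minor_count)
    S <- n_sites(sites)
    out$n_sites[ck] <- S
    if (S < 3L) next
    ldm <- matrix(NA_real_, S, S)
    for (i in 1:(S - 1L)) for (j in (i + 1L):S) {
      st <- ld_statistics(sites$geno[, i], sites$geno[, j])
      if (st$usable)
        ldm[i, j] <- ldm[j, i] <- if (stat == "r2") st$r2 else st$D_prime
    }
    pos <- sites$sites$pos
    dm <- abs(outer(pos, pos, "-"))
    lt <- lower.tri(ldm)
    obs <- suppressWarnings(stats::cor(ldm[lt], dm[lt],
                                       use = "complete.obs"))
    if (is.na(obs)) next
    perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      pp <- sample.int(S)
      lp <- ldm[pp, pp]
      perm[b] <- suppressWarnings(stats::cor(lp[lt], dm[lt],
                                             use = "complete.obs"))
    }
    perm <- perm[!is.na(perm)]
    p <- if (alternative == "negative") .perm_p(perm, obs, "le") else
      min(1, 2 * min(.perm_p(perm, obs, "le"), .perm_p(perm, obs, "ge")))
    out$statistic[ck] <- obs
    out$p_value[ck] <- p
    out$n_perm[ck] <- length(perm)
    out$testable[ck] <- TRUE
  }
  out
}

# per-pair maximum chi-square over sliding windows of w ordered sites split
# at the midpoint; diff is the 0/1 difference vector at the pair's usable
# sites.  Returns max chi2 and the index (into `diff`) of the best split.
.maxchi_pair <- function(diff, w) {
  S <- length(diff)
  if (S < w) return(c(-Inf, NA))
  w2 <- w %/% 2L
  cs <- c(0, cumsum(diff))
  starts <- 1:(S - w + 1L)
  dL <- cs[starts + w2] - cs[starts]
  dR <- cs[starts + w] - cs[starts + w2]
  aL <- w2 - dL; aR <- (w - w2) - dR
  num <- w * (dL * aR - dR * aL)^2
  den <- (dL + aL) * (dR + aR) * (dL + dR) * (aL + aR)
  chi <- ifelse(den > 0, num / den, 0)
  best <- which.max(chi)
  c(chi[best], starts[best] + w2)   # split between site best+w2-1 and next
}

#' Maximum chi-square test for recombination
#'
#' Maynard Smith's max-chi-square over sequence pairs: for each pair, a
#' window of `w = round(window_fraction * S)` ordered segregating sites
#' slides along the alignment and is split at its midpoint; the 2x2
#' chi-square of (differ/agree) x (left/right half) measures how contingent
#' the pair's difference density is on position. The statistic is the
#' maximum over all pairs and window placements; significance comes from
#' permuting the order of segregating sites.
#'
#' @param aln An [mt_alignment].
#' @param window_fraction Window size as a fraction of the segregating-site
#'   count (default 2/3).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @param region Optional 0-based half-open `c(start, end)` restricting the
#'   test to a subregion (e.g. a homing-endonuclease-free interval).
#' @param min_minor_count Minimum minor-allele count for a site.
#' @return An `mt_test` with `statistic` (max chi-square), `p_value`,
#'   `breakpoint_site` (index into the ordered site list after which the
#'   best split falls), `breakpoint_column` (0-based alignment column) and
#'   `n_splits_per_pair`.
#' @export
max_chi2_test <- function(aln, window_fraction = 2 / 3, n_perm = 999L,
                          seed = NULL, region = NULL, min_minor_count = 1L) {
  stopifnot(inherits(aln, "mt_alignment"))
  if (!is.null(seed)) set.seed(seed)
  sites <- extract_biallelic_sites(aln, min_minor_count = min_minor_count)
  if (!is.null(region)) {
    keep <- sites$sites$pos >= region[1L] & sites$sites$pos < region[2L]
    sites$sites <- sites$sites[keep, , drop = FALSE]
    sites$geno <- sites$geno[, keep, drop = FALSE]
  }
  S <- n_sites(sites)
  if (S < 4L) stop("need >= 4 segregating sites")
  w <- as.integer(round(window_fraction * S))
  if (w < 4L) stop("parameter error: window w = ", w, " < 4")
  G <- sites$geno
  n <- nrow(G)
  pairs <- utils::combn(n, 2L)
  pair_diffs <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- G[pairs[1L, p], ]; b <- G[pairs[2L, p], ]
    ok <- !is.na(a) & !is.na(b)
    list(ok = ok, diff = as.integer(a[ok] != b[ok]),
         sitemap = which(ok))
  })
  eval_all <- function(order_perm) {
    best <- c(-Inf, NA, NA)
    for (p in seq_along(pair_diffs)) {
      pd <- pair_diffs[[p]]
      keep <- order_perm[order_perm %in% pd$sitemap]
      dvec <- as.integer(G[pairs[1L, p], keep] != G[pairs[2L, p], keep])
      res <- .maxchi_pair(dvec, w)
      if (res[1L] > best[1L]) best <- c(res[1L], res[2L], p)
    }
    best
  }
  obs <- eval_all(seq_len(S))
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm))
    perm[b] <- eval_all(sample.int(S))[1L]
  p <- .perm_p(perm, obs[1L], "ge")
  bp_site <- obs[2L]
  bp_col <- if (!is.na(bp_site) && bp_site <= S) sites$sites$pos[bp_site] else NA
  .mt_test(obs[1L], p, n_perm, "maximum chi-square",
           breakpoint_site = bp_site, breakpoint_column = bp_col,
           n_splits_per_pair = S - w + 1L, window_sites = w,
           n_sites = S)
}

#' Pairwise homoplasy index (PHI) test
#'
#' Computes the pairwise homoplasy index over parsimony-informative sites
#' within physical distance `window` of each other: for a pair of biallelic
#' sites the refined incompatibility score is 0 when the pair passes the
#' four-gamete condition and 1 (one extra state change required) otherwise;
#' Phi_w is the mean score. Significance is assessed by permuting site
#' positions (which reassigns which pairs fall within the window), or by a
#' normal approximation to that permutation distribution.
#'
#' @param aln An [mt_alignment].
#' @param window Physical distance window in bp (default 100).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @param region Optional 0-based half-open `c(start, end)` subregion.
#' @param method `"permutation"` (default) or `"normal"`.
#' @return An `mt_test` with `statistic` (Phi_w), `p_value`,
#'   `n_informative` and `n_pairs_in_window`; `p_value` is NA with
#'   `testable = FALSE` when no informative pair falls within the window.
#' @export
phi_test <- function(aln, window = 100L, n_perm = 999L, seed = NULL,
                     region = NULL, method = c("permutation", "normal")) {
  stopifnot(inherits(aln, "mt_alignment"))
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  sites <- extract_biallelic_sites(aln, min_minor_count = 2L)
  if (!is.null(region)) {
    keep <- sites$sites$pos >= region[1L] & sites$sites$pos < region[2L]
    sites$sites <- sites$sites[keep, , drop = FALSE]
    sites$geno <- sites$geno[, keep, drop = FALSE]
  }
  S <- n_sites(sites)
  if (S < 2L) stop("need >= 2 informative sites")
  pc <- .pair_counts(sites$geno)
  viol <- (pc$n11 > 0 & pc$n10 > 0 & pc$n01 > 0 & pc$n00 > 0) * 1
  pos <- sites$sites$pos
  L <- sites$alignment_length
  dist_of <- function(p) {
    d <- abs(outer(p, p, "-"))
    if (isTRUE(sites$circular)) d <- pmin(d, L - d)
    d
  }
  ut <- upper.tri(viol)
  phi_of <- function(p) {
    inw <- dist_of(p) <= window & ut
    if (!any(inw)) return(NA_real_)
    mean(viol[inw])
  }
  obs <- phi_of(pos)
  if (is.na(obs))
    return(.mt_test(NA_real_, NA_real_, 0L, "PHI", testable = FALSE,
                    n_informative = S, n_pairs_in_window = 0L))
  # recombination makes nearby pairs LESS incompatible than random site
  # arrangements, so small Phi_w is the signal: count permutations <= obs
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) perm[b] <- phi_of(sample(pos))
  perm <- perm[!is.na(perm)]
  p <- if (method == "permutation") .perm_p(perm, obs, "le") else {
    mu <- mean(perm); sdv <- stats::sd(perm)
    if (sdv == 0) as.numeric(obs >= mu) else
      stats::pnorm(obs, mu, sdv, lower.tail = TRUE)
  }
  .mt_test(obs, p, length(perm), "PHI", testable = TRUE,
           n_informative = S,
           n_pairs_in_window = sum(dist_of(pos) <= window & ut))
}
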