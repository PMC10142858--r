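#' Build a discriminating k-mer library between two mitotypes
#'
#' Enumerates every k-length window of mitotype `type_x` on its circular
#' ungapped sequence and keeps the distinct k-mers that (1) do not span any
#' alignment gap column between the two types and (2) differ by at least
#' `min_diff` nucleotides from every k-mer of `type_y`. Reads matching such
#' a k-mer can then be attributed to type x rather than type y even in the
#' presence of a sequencing error (hence the default `min_diff = 2`).
#'
#' @param aln An [mt_alignment] (or `mt_mitotypes`) containing both types.
#' @param type_x,type_y Row identifiers of the two types; the library
#'   contains k-mers OF `type_x` discriminating it FROM `type_y`.
#' @param k K-mer length in bp (conventionally the read length, e.g. 251).
#' @param min_diff Minimum Hamming distance to every type-y k-mer.
#' @return An object of class `mt_kmerlib`: list with `type_x_id`,
#'   `type_y_id`, `k`, `min_diff`, `kmers` (sorted distinct k-mers),
#'   `size` (#distinct), `n_windows` (positional windows kept, duplicates
#'   uncollapsed).
#' @export
build_kmer_library <- function(aln, type_x, type_y, k = 251L, min_diff = 2L) {
  if (inherits(aln, "mt_mitotypes")) aln <- mitotype_alignment(aln)
  stopifnot(inherits(aln, "mt_alignment"))
  if (!type_x %in% rownames(aln) || !type_y %in% rownames(aln))
    stop("both types must be rows of the alignment")
  cx <- unclass(aln)[type_x, ]
  cy <- unclass(aln)[type_y, ]
  gapcol <- cx == "-" | cy == "-"
  windows_of <- function(chars, other_gapcol) {
    keep <- chars != "-"
    raw <- chars[keep]
    cols <- which(keep)          # alignment column (1-based) of each base
    L <- length(raw)
    if (k > L) stop("parameter error: k exceeds ungapped sequence length")
    circular <- isTRUE(attr(aln, "circular"))
    n_win <- if (circular) L else L - k + 1L
    dbl <- paste(c(raw, raw), collapse = "")
    kmers <- substring(dbl, seq_len(n_win), seq_len(n_win) + k - 1L)
    # footprint = alignment-column interval from first to last covered base
    # (wrapping); drop windows whose footprint contains a gap column
    gap_cum <- c(0L, cumsum(other_gapcol))
    nc <- length(other_gapcol)
    has_gap <- vapply(seq_len(n_win), function(i) {
      c1 <- cols[i]
      j <- i + k - 1L
      c2 <- cols[if (j > L) j - L else j]
      if (c1 <= c2 && j <= L) gap_cum[c2 + 1L] - gap_cum[c1] > 0L
      else (gap_cum[nc + 1L] - gap_cum[c1]) + gap_cum[c2 + 1L] > 0L
    }, logical(1))
    kmers[!has_gap]
  }
  xw <- windows_of(cx, gapcol)
  yw <- unique(windows_of(cy, gapcol))
  if (length(xw) == 0L || length(yw) == 0L)
    kept <- character(0)
  else {
    xun <- unique(xw)
    keep <- .kmer_filter_cpp(xun, yw, as.integer(min_diff))
    kept <- xun[keep]
  }
  structure(list(type_x_id = type_x, type_y_id = type_y, k = as.integer(k),
                 min_diff = as.integer(min_diff),
                 kmers = sort(kept), size = length(kept),
                 n_windows = sum(xw %in% kept)),
            class = "mt_kmerlib")
}

#' @export
print.mt_kmerlib <- function(x, ...) {
  cat(sprintf("mt_kmerlib K[%s|%s]: %d distinct %d-mers (min_diff %d)\n",
              x$type_x_id, x$type_y_id, x$size, x$k, x$min_diff))
  invisible(x)
}

#' Build all pairwise k-mer libraries among a set of mitotypes
#'
#' @param aln An [mt_alignment] or `mt_mitotypes`.
#' @param types Row identifiers; defaults to all rows.
#' @inheritParams build_kmer_library
#' @return Named list of `mt_kmerlib`, keys `"x|y"` for the library of
#'   type-x k-mers discriminating from type y.
#' @export
build_all_kmer_libraries <- function(aln, types = NULL, k = 251L,
                                     min_diff = 2L) {
  if (inherits(aln, "mt_mitotypes")) aln <- mitotype_alignment(aln)
  if (is.null(types)) types <- rownames(aln)
  libs <- list()
  for (x in types) for (y in types) {
    if (x == y) next
    libs[[paste(x, y, sep = "|")]] <-
      build_kmer_library(aln, x, y, k = k, min_diff = min_diff)
  }
  libs
}

#' Estimate heteroplasmy from discriminating k-mer read counts
#'
#' For each candidate minor mitotype i, counts the reads exactly matching a
#' k-mer of `K[i|M]` (reads attributable to i, not the major type M) and of
#' `K[M|i]`, and normalizes each by the library size:
#' `H_i = (#R_iM / #K_iM) / (#R_iM / #K_iM + #R_Mi / #K_Mi)`.
#' The reported heteroplasmy is `H_i` for the candidate maximizing the
#' normalized minor rate `#R_iM / #K_iM` -- a true minor mitotype produces a
#' higher discriminating-read rate than sequencing error does against an
#' arbitrary candidate. Matching is exact full-length identity, by default
#' on either strand; reads whose length differs from k are excluded (and
#' counted).
#'
#' @param reads An `mt_readset` or character vector of reads.
#' @param major Label of the major (assembled) mitotype M.
#' @param candidates Labels of putative minor mitotypes (M itself is
#'   ignored if present).
#' @param libraries Named list from [build_all_kmer_libraries()] (keys
#'   `"x|y"`).
#' @param match_revcomp Match reverse-complemented reads too (default TRUE).
#' @return An object of class `mt_heteroplasmy`: list with `per_candidate`
#'   (data.frame: candidate, n_R_iM, n_K_iM, n_R_Mi, n_K_Mi, minor_rate,
#'   H_hat_i, skipped, reason), `selected_candidate`, `H_hat`,
#'   `zero_denominator` flag, `n_reads_used`, `n_reads_excluded`.
#' @export
estimate_heteroplasmy <- function(reads, major, candidates, libraries,
                                  match_revcomp = TRUE) {
  rv <- if (inherits(reads, "mt_readset")) reads$reads else as.character(reads)
  candidates <- setdiff(candidates, major)
  if (length(candidates) == 0L) stop("no candidates distinct from major")
  per <- data.frame(candidate = candidates, n_R_iM = NA_integer_,
                    n_K_iM = NA_integer_, n_R_Mi = NA_integer_,
                    n_K_Mi = NA_integer_, minor_rate = NA_real_,
                    H_hat_i = NA_real_, skipped = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  k <- NULL
  for (key in names(libraries)) { k <- libraries[[key]]$k; break }
  if (is.null(k)) stop("no libraries supplied")
  len_ok <- nchar(rv) == k
  used <- rv[len_ok]
  rc <- if (match_revcomp && length(used)) .revcomp_cpp(used) else NULL
  count_hits <- function(lib) {
    if (lib$size == 0L) return(0L)
    hits <- used %in% lib$kmers
    if (!is.null(rc)) hits <- hits | (rc %in% lib$kmers)
    sum(hits)
  }
  for (r in seq_len(nrow(per))) {
    i <- per$candidate[r]
    kiM <- libraries[[paste(i, major, sep = "|")]]
    kMi <- libraries[[paste(major, i, sep = "|")]]
    if (is.null(kiM) || is.null(kMi)) {
      per$skipped[r] <- TRUE; per$reason[r] <- "library missing"; next
    }
    if (kiM$size == 0L || kMi$size == 0L) {
      per$skipped[r] <- TRUE; per$reason[r] <- "empty library"; next
    }
    per$n_K_iM[r] <- kiM$size; per$n_K_Mi[r] <- kMi$size
    per$n_R_iM[r] <- count_hits(kiM)
    per$n_R_Mi[r] <- count_hits(kMi)
    num <- per$n_R_iM[r] / per$n_K_iM[r]
    den <- num + per$n_R_Mi[r] / per$n_K_Mi[r]
    per$minor_rate[r] <- num
    per$H_hat_i[r] <- if (den > 0) num / den else 0
  }
  ok <- !per$skipped
  if (!any(ok)) stop("estimation error: all candidates skipped")
  best <- which(ok)[order(-per$minor_rate[ok], per$candidate[ok])][1L]
  zero_den <- per$minor_rate[best] == 0 && per$n_R_Mi[best] == 0L
  structure(list(per_candidate = per,
                 major_type = major,
                 selected_candidate = per$candidate[best],
                 H_hat = per$H_hat_i[best],
                 zero_denominator = zero_den,
                 n_reads_used = sum(len_ok),
                 n_reads_excluded = sum(!len_ok)),
            class = "mt_heteroplasmy")
}

#' @export
print.mt_heteroplasmy <- function(x, ...) {
  cat(sprintf("mt_heteroplasmy: H_hat = %.4g (candidate %s vs major %s)\n",
              x$H_hat, x$selected_candidate, x$major_type))
  invisible(x)
}

#' Right-tail outlier detection under a fitted beta distribution
#'
#' Fits a beta distribution to the bulk of the values by least-squares
#' regression of the central order statistics on the corresponding beta
#' quantiles (extreme quantiles excluded from the fit), then flags value v
#' as a right-tail outlier when the expected number of observations >= v
#' under the fitted model, `N * (1 - F(v))`, falls below `rho`.
#'
#' @param values Proportions in `[0, 1]`, at least 5 of them.
#' @param rho Expected-outlier-count threshold (default 1).
#' @param fit_limits Quantile range used for the fit (default `c(0.1, 0.9)`).
#' @return List of class `mt_outliers` with `outlier` (logical per value),
#'   `expected_ge` (N*(1-F(v)) per value), `shape1`, `shape2`, `degenerate`.
#' @export
beta_outlier_detection <- function(values, rho = 1,
                                   fit_limits = c(0.1, 0.9)) {
  if (any(values < 0 | values > 1)) stop("values must be in [0, 1]")
  N <- length(values)
  if (N < 5L) stop("need >= 5 values")
  if (rho >= N) {
    # expected-outlier budget covers the whole sample: degenerate threshold
    return(structure(list(outlier = rep(FALSE, N),
                          expected_ge = rep(NA_real_, N),
                          shape1 = NA_real_, shape2 = NA_real_,
                          degenerate = TRUE), class = "mt_outliers"))
  }
  if (stats::var(values) == 0) {
    return(structure(list(outlier = rep(FALSE, N),
                          expected_ge = rep(NA_real_, N),
                          shape1 = NA_real_, shape2 = NA_real_,
                          degenerate = TRUE), class = "mt_outliers"))
  }
  ys <- sort(values)
  pp <- seq_len(N) / (N + 1)
  sel <- pp >= fit_limits[1L] & pp <= fit_limits[2L]
  yfit <- ys[sel]; pfit <- pp[sel]
  m <- mean(yfit); v <- stats::var(yfit)
  v <- max(v, 1e-12)
  common <- max(m * (1 - m) / v - 1, 0.1)
  par0 <- log(c(max(m * common, 1e-3), max((1 - m) * common, 1e-3)))
  obj <- function(lp) {
    q <- stats::qbeta(pfit, exp(lp[1L]), exp(lp[2L]))
    sum((q - yfit)^2)
  }
  fit <- stats::optim(par0, obj, method = "Nelder-Mead")
  a <- exp(fit$par[1L]); b <- exp(fit$par[2L])
  expected <- N * stats::pbeta(values, a, b, lower.tail = FALSE)
  structure(list(outlier = expected < rho, expected_ge = expected,
                 shape1 = a, shape2 = b, degenerate = FALSE),
            class = "mt_outliers")
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum comparison of two groups with midrank tie handling.
#' For combined sample sizes up to 12 the permutation distribution of U is
#' enumerated exhaustively; larger samples use the normal approximation
#' with the tie-corrected variance.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return An `mt_test` with `statistic` (U of group a), `p_value` and
#'   `method` recording whether the exact or approximate path was used.
#' @export
mann_whitney_test <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  mid <- na * nb / 2
  if (n <= 12L) {
    combos <- utils::combn(n, na)
    devs <- apply(combos, 2L, function(ix)
      abs(sum(rk[ix]) - na * (na + 1) / 2 - mid))
    p <- mean(devs >= abs(U - mid) - 1e-9)
    method <- "Mann-Whitney (exact)"
  } else {
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) { p <- 1; method <- "Mann-Whitney (normal, degenerate)" }
    else {
      z <- (U - mid) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
      method <- "Mann-Whitney (normal approximation)"
    }
  }
  .mt_test(U, min(p, 1), 0L, method, n_a = na, n_b = nb)
}
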