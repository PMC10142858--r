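#' Collapse alignment rows into mitotypes
#'
#' Samples whose sequences are identical after masking unreliable columns
#' are merged into a single mitotype. Two classes of columns are masked
#' before comparison, reflecting the dominant artefact modes of short-read
#' mitogenome assemblies: (1) columns inside or immediately flanking a
#' homopolymer run of length >= `homopolymer_min` in the majority-consensus
#' sequence (single-nucleotide repeats cause assembly slippage); (2) columns
#' inside any window of `gappy_window` columns whose overall gap fraction is
#' >= `gappy_fraction` (alignment-ambiguous gappy regions).
#'
#' @param aln An [mt_alignment].
#' @param homopolymer_min Minimum homopolymer run length that triggers
#'   masking (default 5).
#' @param gappy_window Sliding window width in columns (default 11).
#' @param gappy_fraction Gap fraction within a window at which the whole
#'   window is masked (default 0.2).
#' @return An object of class `mt_mitotypes`: list with `mitotypes` (each a
#'   list of `id`, `member_sample_ids`, `representative` full-length gapped
#'   string), `masked_columns` (0-based), and the source alignment's
#'   dimensions and circularity.
#' @export
collapse_mitotypes <- function(aln, homopolymer_min = 5L, gappy_window = 11L,
                               gappy_fraction = 0.2) {
  stopifnot(inherits(aln, "mt_alignment"))
  m <- unclass(aln)
  nc <- ncol(m)
  # majority consensus (gaps participate; ties broken alphabetically)
  cons <- apply(m, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1L]
  })
  masked <- logical(nc)
  # homopolymer runs in the consensus (gap runs don't count as repeats)
  r <- rle(cons)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$lengths >= homopolymer_min & r$values %in% c("A", "C", "G", "T"))) {
    lo <- max(1L, starts[i] - 1L)
    hi <- min(nc, ends[i] + 1L)
    masked[lo:hi] <- TRUE
  }
  # gappy windows
  if (nc >= gappy_window) {
    isgap <- colMeans(m == "-")
    cs <- c(0, cumsum(isgap))
    for (s in 1:(nc - gappy_window + 1L)) {
      frac <- (cs[s + gappy_window] - cs[s]) / gappy_window
      if (frac >= gappy_fraction) masked[s:(s + gappy_window - 1L)] <- TRUE
    }
  }
  keep <- which(!masked)
  key <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  groups <- split(seq_len(nrow(m)), factor(key, levels = unique(key)))
  full <- apply(m, 1L, paste, collapse = "")
  mts <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    reps <- table(full[rows])
    mts[[g]] <- list(id = sprintf("MT%02d", g),
                     member_sample_ids = rownames(m)[rows],
                     representative = names(sort(reps, decreasing = TRUE))[1L])
  }
  structure(list(mitotypes = mts,
                 masked_columns = which(masked) - 1L,
                 alignment_length = nc,
                 circular = attr(aln, "circular")),
            class = "mt_mitotypes")
}

#' @export
print.mt_mitotypes <- function(x, ...) {
  cat(sprintf("mt_mitotypes: %d mitotypes from %d samples (%d masked columns)\n",
              length(x$mitotypes),
              sum(lengths(lapply(x$mitotypes, `[[`, "member_sample_ids"))),
              length(x$masked_columns)))
  invisible(x)
}

#' Mitotypes as an alignment of representatives
#' @param mts An `mt_mitotypes`.
#' @return An [mt_alignment] with one row per mitotype.
#' @export
mitotype_alignment <- function(mts) {
  stopifnot(inherits(mts, "mt_mitotypes"))
  seqs <- vapply(mts$mitotypes, `[[`, character(1), "representative")
  ids <- vapply(mts$mitotypes, `[[`, character(1), "id")
  mt_alignment(seqs, sample_ids = ids, circular = mts$circular)
}

#' Extract biallelic segregating sites
#'
#' Scans alignment columns and keeps those with exactly two alleles among
#' `A C G T` across non-gap, non-N entries, with minor-allele count at least
#' `min_minor_count`. Gap and N entries are recorded as missing, never
#' imputed. When given an `mt_mitotypes` object, representatives are scanned
#' and masked columns are excluded.
#'
#' @param x An [mt_alignment] or `mt_mitotypes`.
#' @param min_minor_count Minimum minor-allele count (default 1; the
#'   single-minor-allele filter used for noisier nuclear data corresponds
#'   to 2).
#' @return An object of class `mt_sites`: list with `sites` (data.frame of
#'   0-based `pos`, `major`, `minor`, `minor_count`), `geno` (samples x
#'   sites matrix coded 0 = major, 1 = minor, NA = missing),
#'   `alignment_length`, `circular`, `sample_ids`.
#' @export
extract_biallelic_sites <- function(x, min_minor_count = 1L) {
  excluded <- integer(0)
  if (inherits(x, "mt_mitotypes")) {
    excluded <- x$masked_columns
    x <- mitotype_alignment(x)
  }
  stopifnot(inherits(x, "mt_alignment"), nrow(x) >= 2L)
  m <- unclass(x)
  nc <- ncol(m)
  use_col <- rep(TRUE, nc)
  use_col[excluded + 1L] <- FALSE
  pos <- integer(0); major <- character(0); minor <- character(0)
  mc <- integer(0); geno_cols <- list()
  bases <- c("A", "C", "G", "T")
  for (j in which(use_col)) {
    col <- m[, j]
    ok <- col %in% bases
    tb <- table(col[ok])
    if (length(tb) != 2L) next
    # major = most frequent; alphabetical tie-break for determinism
    o <- order(-tb, names(tb))
    if (tb[o[2L]] < min_minor_count) next
    pos <- c(pos, j - 1L)
    major <- c(major, names(tb)[o[1L]])
    minor <- c(minor, names(tb)[o[2L]])
    mc <- c(mc, as.integer(tb[o[2L]]))
    g <- rep(NA_integer_, nrow(m))
    g[ok] <- as.integer(col[ok] == names(tb)[o[2L]])
    geno_cols[[length(geno_cols) + 1L]] <- g
  }
  geno <- if (length(geno_cols)) do.call(cbind, geno_cols) else
    matrix(integer(0), nrow(m), 0L)
  rownames(geno) <- rownames(m)
  structure(list(sites = data.frame(pos = pos, major = major, minor = minor,
                                    minor_count = mc,
                                    stringsAsFactors = FALSE),
                 geno = geno,
                 alignment_length = nc,
                 circular = attr(x, "circular"),
                 sample_ids = rownames(m)),
            class = "mt_sites")
}

#' @export
print.mt_sites <- function(x, ...) {
  cat(sprintf("mt_sites: %d biallelic sites over %d samples (alignment %d bp, %s)\n",
              nrow(x$sites), length(x$sample_ids), x$alignment_length,
              if (isTRUE(x$circular)) "circular" else "linear"))
  invisible(x)
}

#' Number of segregating sites
#' @param sites An `mt_sites`.
#' @return Integer count.
#' @export
n_sites <- function(sites) nrow(sites$sites)

#' Minimum-spanning haplotype network of mitotypes
#'
#' Builds a minimum-spanning network on pairwise Hamming distances between
#' mitotype representatives (masked columns excluded; columns where either
#' representative has a gap or N are skipped pairwise). Kruskal-style
#' construction in which, at each distance level, every edge joining two
#' distinct components is retained before components merge -- so ties at
#' equal distance are all kept.
#'
#' @param mts An `mt_mitotypes` with >= 2 mitotypes.
#' @return A data.frame with columns `from_mitotype`, `to_mitotype`,
#'   `n_differences`.
#' @export
haplotype_network <- function(mts) {
  stopifnot(inherits(mts, "mt_mitotypes"))
  k <- length(mts$mitotypes)
  if (k < 2L) stop("need >= 2 mitotypes")
  ids <- vapply(mts$mitotypes, `[[`, character(1), "id")
  seqm <- do.call(rbind, strsplit(vapply(mts$mitotypes, `[[`, character(1),
                                         "representative"), ""))
  if (length(mts$masked_columns))
    seqm <- seqm[, -(mts$masked_columns + 1L), drop = FALSE]
  good <- seqm %in% c("A", "C", "G", "T")
  dim(good) <- dim(seqm)
  pairs <- utils::combn(k, 2L)
  dist <- integer(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    ok <- good[i, ] & good[j, ]
    dist[p] <- sum(seqm[i, ok] != seqm[j, ok])
  }
  comp <- seq_len(k)
  edges <- data.frame(from_mitotype = character(0), to_mitotype = character(0),
                      n_differences = integer(0), stringsAsFactors = FALSE)
  for (w in sort(unique(dist))) {
    lvl <- which(dist == w)
    joining <- lvl[comp[pairs[1L, lvl]] != comp[pairs[2L, lvl]]]
    for (p in joining)
      edges <- rbind(edges, data.frame(from_mitotype = ids[pairs[1L, p]],
                                       to_mitotype = ids[pairs[2L, p]],
                                       n_differences = dist[p],
                                       stringsAsFactors = FALSE))
    for (p in joining) {          # merge after collecting the whole level
      ca <- comp[pairs[1L, p]]; cb <- comp[pairs[2L, p]]
      if (ca != cb) comp[comp == cb] <- ca
    }
    if (length(unique(comp)) == 1L) break
  }
  edges
}
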