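#' Nucleotide diversity (pi)
#'
#' Average over all sequence pairs of the proportion of differing sites,
#' with pairwise deletion: for each pair only columns where both sequences
#' carry an unambiguous base (`A C G T`) are compared. Optionally also
#' computed in non-overlapping windows of alignment columns.
#'
#' @param aln An [mt_alignment] with >= 2 sequences.
#' @param window Optional window width in alignment columns; if given,
#'   per-window pi values are returned alongside the global value.
#' @return An object of class `mt_diversity`: list with `pi`,
#'   `window_values` (data.frame `start`, `end`, `pi`, `n_pairs_used` or
#'   NULL), `n_sequences`, `n_sites_used` (mean compared sites per pair).
#' @export
nucleotide_diversity <- function(aln, window = NULL) {
  stopifnot(inherits(aln, "mt_alignment"), nrow(aln) >= 2L)
  m <- unclass(aln)
  good <- m %in% c("A", "C", "G", "T")
  dim(good) <- dim(m)
  pairs <- utils::combn(nrow(m), 2L)
  np <- ncol(pairs)
  calc <- function(colsel) {
    tot_diff <- 0; tot_comp <- 0; vals <- numeric(0)
    props <- rep(NA_real_, np)
    for (p in seq_len(np)) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      ok <- good[i, colsel] & good[j, colsel]
      nc <- sum(ok)
      if (nc == 0L) next
      props[p] <- sum(m[i, colsel][ok] != m[j, colsel][ok]) / nc
      tot_comp <- tot_comp + nc
    }
    if (all(is.na(props))) return(list(pi = NA_real_, comp = 0, used = 0))
    list(pi = mean(props, na.rm = TRUE), comp = tot_comp / np,
         used = sum(!is.na(props)))
  }
  all_cols <- seq_len(ncol(m))
  g <- calc(all_cols)
  if (is.na(g$pi)) stop("all columns gapped or ambiguous")
  wv <- NULL
  if (!is.null(window)) {
    starts <- seq(1L, ncol(m), by = window)
    wv <- data.frame(start = starts - 1L,
                     end = pmin(starts + window - 1L, ncol(m)),
                     pi = NA_real_, n_pairs_used = 0L)
    for (r in seq_along(starts)) {
      res <- calc(starts[r]:min(starts[r] + window - 1L, ncol(m)))
      wv$pi[r] <- res$pi
      wv$n_pairs_used[r] <- res$used
    }
  }
  structure(list(pi = g$pi, window_values = wv, n_sequences = nrow(m),
                 n_sites_used = g$comp),
            class = "mt_diversity")
}

# significant-figure rounding with ties away from zero (reported values
# follow the usual print convention, not round-half-even)
.signif_half_up <- function(x, digits = 2L) {
  if (x == 0) return(0)
  m <- 10^(floor(log10(abs(x))) - digits + 1L)
  sign(x) * floor(abs(x) / m + 0.5 + 1e-9) * m
}

#' Ne*mu under an inheritance model
#'
#' Converts per-site nucleotide diversity into the product of effective
#' population size and mutation rate using the expectation of theta for the
#' inheritance mode: theta = 2*Ne*mu for a uniparentally inherited haploid
#' genome (mitochondria), theta = 4*Ne*mu for biparental diploid genomes
#' (nuclei). Summaries round to 2 significant figures.
#'
#' @param pi Per-site nucleotide diversity (>= 0).
#' @param inheritance `"uniparental_haploid"` or `"biparental_diploid"`.
#' @return List of class `mt_nemu` with `ne_mu`, `ne_mu_2sf` and
#'   `inheritance`.
#' @export
ne_mu <- function(pi, inheritance = c("uniparental_haploid",
                                      "biparental_diploid")) {
  inheritance <- match.arg(inheritance)
  if (!is.numeric(pi) || pi < 0) stop("pi must be >= 0")
  v <- if (inheritance == "uniparental_haploid") pi / 2 else pi / 4
  structure(list(ne_mu = v, ne_mu_2sf = .signif_half_up(v, 2L),
                 inheritance = inheritance), class = "mt_nemu")
}

# genetic code tables; "mold_mito" is translation table 4 (TGA = Trp)
.genetic_code <- function(code = c("standard", "mold_mito")) {
  code <- match.arg(code)
  gc <- Biostrings::GENETIC_CODE
  if (code == "mold_mito") gc[["TGA"]] <- "W"
  gc
}

# Per-codon synonymous site count under transition/transversion weighting:
# at each position the three possible changes carry weights tstv (the one
# transition) and 1 (each transversion); the synonymous site fraction is the
# weight share of synonymous changes, so syn + nonsyn sites always sum to 3.
# Changes creating a stop codon count as nonsynonymous.
.codon_syn_sites <- function(codon, gc, tstv) {
  aa <- gc[[codon]]
  if (is.na(aa) || aa == "*") return(NA_real_)
  bases <- c("A", "C", "G", "T")
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  s <- 0
  ch <- strsplit(codon, "")[[1]]
  for (p in 1:3) {
    for (b in setdiff(bases, ch[p])) {
      mut <- ch; mut[p] <- b
      mcod <- paste(mut, collapse = "")
      w <- if (b == ts_of[[ch[p]]]) tstv else 1
      if (gc[[mcod]] == aa) s <- s + w / (tstv + 2)
    }
  }
  s
}

# Synonymous/nonsynonymous differences between two codons, averaged over all
# orderings of single-step mutational paths; paths through stop codons are
# excluded unless every path hits a stop.
.codon_pair_diffs <- function(c1, c2, gc) {
  if (c1 == c2) return(c(0, 0))
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  dpos <- which(ch1 != ch2)
  perms <- switch(length(dpos),
                  list(dpos),
                  list(dpos, rev(dpos)),
                  {p <- dpos; list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                                   p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])})
  eval_path <- function(ord) {
    cur <- ch1; sd <- 0; nd <- 0; hit_stop <- FALSE
    for (p in ord) {
      prev_cod <- paste(cur, collapse = "")
      cur[p] <- ch2[p]
      new_cod <- paste(cur, collapse = "")
      if (gc[[new_cod]] == "*" && new_cod != c2) hit_stop <- TRUE
      if (gc[[new_cod]] == gc[[prev_cod]] && gc[[new_cod]] != "*")
        sd <- sd + 1 else nd <- nd + 1
    }
    c(sd, nd, hit_stop)
  }
  res <- t(vapply(perms, eval_path, numeric(3)))
  ok <- res[, 3L] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(res))
  c(mean(res[ok, 1L]), mean(res[ok, 2L]))
}

#' Synonymous and nonsynonymous diversity (modified Nei-Gojobori)
#'
#' Computes per-site synonymous (pi_s) and nonsynonymous (pi_n) diversity on
#' a codon-aware alignment using the modified Nei-Gojobori method: potential
#' site counts weight the single transition at each codon position by `tstv`
#' and each transversion by 1, and observed differences between codons
#' differing at more than one position are averaged over all orderings of
#' single-step paths (paths through stop codons excluded when avoidable).
#' Codon pairs where either codon contains a gap/ambiguity or encodes a stop
#' are excluded pairwise. No multiple-hit correction is applied.
#'
#' @param aln An [mt_alignment]; its length must be divisible by 3.
#' @param tstv Transition/transversion weight ratio (default 2).
#' @param code Genetic code: `"mold_mito"` (fungal mitochondrial, table 4)
#'   or `"standard"`.
#' @return List of class `mt_codon_diversity` with `pi_n`, `pi_s`, `ratio`
#'   (NA when `pi_s` is 0), `n_syn_sites`, `n_nonsyn_sites` (mean per-pair
#'   fractional site counts), `n_codons`.
#' @export
pn_ps <- function(aln, tstv = 2, code = c("mold_mito", "standard")) {
  stopifnot(inherits(aln, "mt_alignment"))
  code <- match.arg(code)
  if (ncol(aln) %% 3L != 0L)
    stop("format error: alignment length not divisible by 3")
  gc <- .genetic_code(code)
  m <- unclass(aln)
  ncod <- ncol(m) %/% 3L
  codons <- matrix("", nrow(m), ncod)
  for (cix in seq_len(ncod))
    codons[, cix] <- paste0(m[, 3L * cix - 2L], m[, 3L * cix - 1L], m[, 3L * cix])
  valid <- matrix(grepl("^[ACGT]{3}$", codons), nrow(m), ncod)
  sites_memo <- new.env(parent = emptyenv())
  diffs_memo <- new.env(parent = emptyenv())
  syn_sites_of <- function(cod) {
    v <- sites_memo[[cod]]
    if (is.null(v)) {
      v <- .codon_syn_sites(cod, gc, tstv)
      sites_memo[[cod]] <- v
    }
    v
  }
  diffs_of <- function(c1, c2) {
    key <- paste(sort(c(c1, c2)), collapse = "|")
    v <- diffs_memo[[key]]
    if (is.null(v)) {
      v <- .codon_pair_diffs(c1, c2, gc)
      diffs_memo[[key]] <- v
    }
    v
  }
  pairs <- utils::combn(nrow(m), 2L)
  ps <- numeric(0); pn <- numeric(0); Ss <- numeric(0); Ns <- numeric(0)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    S <- 0; sd <- 0; nd <- 0; used <- 0L
    for (cix in seq_len(ncod)) {
      if (!valid[i, cix] || !valid[j, cix]) next
      s1 <- syn_sites_of(codons[i, cix]); s2 <- syn_sites_of(codons[j, cix])
      if (is.na(s1) || is.na(s2)) next   # stop codon in either sequence
      S <- S + (s1 + s2) / 2
      d <- diffs_of(codons[i, cix], codons[j, cix])
      sd <- sd + d[1L]; nd <- nd + d[2L]
      used <- used + 1L
    }
    if (used == 0L) next
    N <- 3 * used - S
    ps <- c(ps, if (S > 0) sd / S else NA_real_)
    pn <- c(pn, if (N > 0) nd / N else NA_real_)
    Ss <- c(Ss, S); Ns <- c(Ns, N)
  }
  if (length(ps) == 0L) stop("no comparable codons")
  pi_s <- mean(ps, na.rm = TRUE)
  pi_n <- mean(pn, na.rm = TRUE)
  structure(list(pi_n = pi_n, pi_s = pi_s,
                 ratio = if (is.finite(pi_s) && pi_s > 0) pi_n / pi_s else NA_real_,
                 n_syn_sites = mean(Ss), n_nonsyn_sites = mean(Ns),
                 n_codons = ncod),
            class = "mt_codon_diversity")
}

#' Bootstrap comparison of mitochondrial vs nuclear pi_n/pi_s
#'
#' Resamples codon columns with replacement, independently in each codon
#' alignment, and reports the fraction of replicates in which the
#' mitochondrial pi_n/pi_s exceeds the nuclear pi_n/pi_s. Replicates where
#' either ratio is undefined (pi_s = 0) count as non-support and are tallied
#' separately.
#'
#' @param mito_aln,nuclear_aln Codon-aware [mt_alignment]s.
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Optional integer seed.
#' @param tstv Transition/transversion weight ratio (default 2).
#' @param mito_code,nuclear_code Genetic codes for the two alignments.
#' @return List of class `mt_bootstrap` with `support` (fraction in
#'   `[0,1]`), `n_boot`, `n_undefined` and the replicate ratio table.
#' @export
bootstrap_ratio_comparison <- function(mito_aln, nuclear_aln, n_boot = 100L,
                                       seed = NULL, tstv = 2,
                                       mito_code = "mold_mito",
                                       nuclear_code = "standard") {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  resample <- function(aln) {
    ncod <- ncol(aln) %/% 3L
    pick <- sample.int(ncod, ncod, replace = TRUE)
    cols <- as.vector(rbind(3L * pick - 2L, 3L * pick - 1L, 3L * pick))
    mt_alignment(unclass(aln)[, cols, drop = FALSE],
                 sample_ids = rownames(aln), circular = FALSE)
  }
  ratio_m <- numeric(n_boot); ratio_n <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ratio_m[b] <- pn_ps(resample(mito_aln), tstv = tstv, code = mito_code)$ratio
    ratio_n[b] <- pn_ps(resample(nuclear_aln), tstv = tstv,
                        code = nuclear_code)$ratio
  }
  supp <- !is.na(ratio_m) & !is.na(ratio_n) & ratio_m > ratio_n
  structure(list(support = mean(supp), n_boot = n_boot,
                 n_undefined = sum(is.na(ratio_m) | is.na(ratio_n)),
                 replicates = data.frame(mito = ratio_m, nuclear = ratio_n)),
            class = "mt_bootstrap")
}
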