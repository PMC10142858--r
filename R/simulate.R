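#' Simulation parameters for the coalescent haplotype generator
#'
#' Bundles and validates the parameters of [simulate_haplotypes()]. Defaults
#' reflect a low-diversity circular fungal mitogenome: per-site population
#' mutation parameter (theta) of 0.003 and no recombination.
#'
#' @param n_samples Number of haploid sequences to sample (>= 2).
#' @param seq_length Sequence length in bp (>= 1).
#' @param theta_site Per-site population mutation parameter, theta = 2*Ne*mu
#'   for a uniparentally inherited haploid genome. Non-negative.
#' @param rho_site Per-site population recombination parameter. Non-negative.
#' @param circular Logical; mark the resulting alignment circular. Simulation
#'   runs on a linear coordinate, circularity affects downstream distances.
#' @param finite_sites Logical; if `TRUE`, recurrent mutation at a column is
#'   allowed (Jukes-Cantor-like overwrite in time order) instead of the
#'   default infinite-sites placement on distinct columns.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_samples, seq_length, theta_site = 0.003,
                       rho_site = 0, circular = TRUE, finite_sites = FALSE,
                       seed = NULL) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2)
    stop("n_samples must be a single number >= 2")
  if (!is.numeric(seq_length) || length(seq_length) != 1L || seq_length < 1)
    stop("seq_length must be a single number >= 1")
  if (!is.numeric(theta_site) || theta_site < 0)
    stop("theta_site must be >= 0")
  if (!is.numeric(rho_site) || rho_site < 0)
    stop("rho_site must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 seq_length = as.integer(seq_length),
                 theta_site = theta_site, rho_site = rho_site,
                 circular = isTRUE(circular),
                 finite_sites = isTRUE(finite_sites),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_params")
}

# Merge the ancestral material of two lineages.  Each lineage is a list with
# numeric matrix `iv` (columns start,end; disjoint, sorted) and `sets`, a
# parallel list of descendant sample indices.  Segments whose merged set
# covers all n samples have found their MRCA and are dropped.
.merge_lineages <- function(a, b, n) {
  bounds <- sort(unique(c(a$iv, b$iv)))
  if (length(bounds) < 2L) return(list(iv = matrix(numeric(0), 0, 2), sets = list()))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  # which interval of each parent covers each elementary segment (midpoint test)
  mid <- (starts + ends) / 2
  ia <- .covering_interval(a$iv, mid)
  ib <- .covering_interval(b$iv, mid)
  keep_iv <- NULL; keep_sets <- list(); k <- 0L
  last_key <- ""
  for (j in seq_along(mid)) {
    s <- integer(0)
    if (!is.na(ia[j])) s <- a$sets[[ia[j]]]
    if (!is.na(ib[j])) s <- union(s, b$sets[[ib[j]]])
    if (length(s) == 0L || length(s) == n) { last_key <- ""; next }
    s <- sort.int(s)
    key <- paste(s, collapse = ",")
    if (k > 0L && key == last_key && keep_iv[k, 2L] == starts[j]) {
      keep_iv[k, 2L] <- ends[j]           # coalesce adjacent identical segments
    } else {
      k <- k + 1L
      keep_iv <- rbind(keep_iv, c(starts[j], ends[j]))
      keep_sets[[k]] <- s
    }
    last_key <- key
  }
  if (k == 0L) return(list(iv = matrix(numeric(0), 0, 2), sets = list()))
  list(iv = keep_iv, sets = keep_sets)
}

# For each query point return the row index of the interval containing it (NA
# if none).  Intervals are disjoint and sorted.
.covering_interval <- function(iv, x) {
  if (nrow(iv) == 0L) return(rep(NA_integer_, length(x)))
  idx <- findInterval(x, iv[, 1L])
  ok <- idx >= 1L & idx <= nrow(iv)
  ok[ok] <- x[ok] < iv[idx[ok], 2L]
  out <- rep(NA_integer_, length(x))
  out[ok] <- idx[ok]
  out
}

.lineage_span <- function(l) {
  if (nrow(l$iv) == 0L) return(0)
  l$iv[nrow(l$iv), 2L] - l$iv[1L, 1L]
}

#' Simulate haplotypes under the coalescent with recombination
#'
#' Runs an ancestral-recombination-graph simulation (Hudson's algorithm with
#' ancestral-material tracking) for `n_samples` sequences of length
#' `seq_length`, placing mutations uniformly on lineages at rate
#' `theta_site/2` per site per unit of coalescent time. Under the default
#' infinite-sites model every mutation occupies its own alignment column, so
#' data simulated with `rho_site = 0` can never show a four-gamete violation.
#'
#' @param params A [sim_params()] object.
#' @return An [mt_alignment] of `n_samples` sequences. Truth metadata is
#'   attached as attribute `"truth"`: a list with the realized number of
#'   recombination events (`n_recomb_events`), the mutated columns
#'   (`mutation_columns`, 0-based) and the per-mutation carrier sets.
#' @examples
#' aln <- simulate_haplotypes(sim_params(5, 2000, theta_site = 0.003, seed = 1))
#' attr(aln, "truth")$n_recomb_events
#' @export
simulate_haplotypes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_samples
  L <- as.numeric(params$seq_length)
  rho <- params$rho_site
  theta <- params$theta_site

  # active lineages, each born at `birth`; branch segments are logged when a
  # lineage dies so mutations can be placed afterwards in one pass
  lineages <- vector("list", n)
  for (i in seq_len(n))
    lineages[[i]] <- list(iv = matrix(c(0, L), 1L, 2L), sets = list(i), birth = 0)
  t_now <- 0
  n_rec <- 0L
  log_start <- numeric(0); log_end <- numeric(0)
  log_dur <- numeric(0); log_sets <- list()
  log_t0 <- numeric(0)

  log_death <- function(l) {
    if (nrow(l$iv) == 0L) return(invisible())
    dur <- t_now - l$birth
    if (dur <= 0) return(invisible())
    m <- nrow(l$iv)
    log_start <<- c(log_start, l$iv[, 1L])
    log_end <<- c(log_end, l$iv[, 2L])
    log_dur <<- c(log_dur, rep(dur, m))
    log_t0 <<- c(log_t0, rep(l$birth, m))
    log_sets <<- c(log_sets, l$sets)
    invisible()
  }

  while (length(lineages) > 1L) {
    k <- length(lineages)
    spans <- vapply(lineages, .lineage_span, numeric(1))
    rate_c <- k * (k - 1) / 2
    rate_r <- rho / 2 * sum(spans)
    t_now <- t_now + stats::rexp(1L, rate_c + rate_r)
    if (stats::runif(1L) < rate_c / (rate_c + rate_r)) {
      pair <- sample.int(k, 2L)
      a <- lineages[[pair[1L]]]; b <- lineages[[pair[2L]]]
      log_death(a); log_death(b)
      merged <- .merge_lineages(a, b, n)
      merged$birth <- t_now
      lineages <- lineages[-pair]
      if (nrow(merged$iv) > 0L) lineages[[length(lineages) + 1L]] <- merged
    } else {
      j <- sample.int(k, 1L, prob = spans)
      l <- lineages[[j]]
      u <- stats::runif(1L, l$iv[1L, 1L], l$iv[nrow(l$iv), 2L])
      n_rec <- n_rec + 1L
      log_death(l)
      left_rows <- which(l$iv[, 1L] < u)
      right_rows <- which(l$iv[, 2L] > u)
      left <- list(iv = l$iv[left_rows, , drop = FALSE],
                   sets = l$sets[left_rows], birth = t_now)
      right <- list(iv = l$iv[right_rows, , drop = FALSE],
                    sets = l$sets[right_rows], birth = t_now)
      left$iv[left$iv[, 2L] > u, 2L] <- u
      right$iv[right$iv[, 1L] < u, 1L] <- u
      lineages[[j]] <- left
      lineages[[length(lineages) + 1L]] <- right
      # either side may carry no material (break in a trapped gap)
      empt <- vapply(lineages, function(x) nrow(x$iv) == 0L, logical(1))
      lineages <- lineages[!empt]
    }
  }

  # place mutations on logged branch segments
  w <- log_dur * (log_end - log_start)
  W <- sum(w)
  n_mut <- if (theta > 0 && W > 0) stats::rpois(1L, theta / 2 * W) else 0L
  mut_col <- integer(0); mut_sets <- list(); mut_time <- numeric(0)
  if (n_mut > 0L) {
    picked <- sample.int(length(w), n_mut, replace = TRUE, prob = w)
    pos <- stats::runif(n_mut, log_start[picked], log_end[picked])
    cols <- floor(pos)
    if (!params$finite_sites) {
      # infinite sites: relocate clashing mutations to unused columns
      for (i in seq_len(n_mut)) {
        if (cols[i] %in% cols[seq_len(i - 1L)]) {
          free <- setdiff(0:(L - 1), cols[seq_len(i - 1L)])
          if (length(free) == 0L) stop("sequence too short for mutation count")
          cols[i] <- if (length(free) == 1L) free else sample(free, 1L)
        }
      }
    }
    mut_col <- as.integer(cols)
    mut_sets <- log_sets[picked]
    mut_time <- log_t0[picked] + stats::runif(n_mut) * log_dur[picked]
  }

  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)
  if (n_mut > 0L) {
    ord <- order(mut_time, decreasing = TRUE)  # oldest first
    for (i in ord) {
      colx <- mut_col[i] + 1L
      cur <- mat[mut_sets[[i]][1L], colx]
      mat[mut_sets[[i]], colx] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  ids <- sprintf("sim%02d", seq_len(n))
  aln <- mt_alignment(mat, sample_ids = ids, circular = params$circular)
  attr(aln, "truth") <- list(n_recomb_events = n_rec,
                             mutation_columns = mut_col,
                             carrier_sets = mut_sets,
                             params = params)
  aln
}

#' Simulate short reads from a two-mitotype heteroplasmic mixture
#'
#' Draws reads of fixed length from a circular genome: each read originates
#' from the minor mitotype with probability `minor_fraction`, otherwise from
#' the major mitotype; start positions are uniform on the circle (reads may
#' wrap the origin) and independent uniform substitution errors are applied
#' at `error_rate` per base. Truth labels are retained for every read.
#'
#' @param major,minor Ungapped nucleotide sequences (single strings).
#' @param minor_fraction Probability a read derives from the minor type.
#' @param depth Target fold-coverage; the number of reads is
#'   `round(depth * nchar(major) / read_length)`.
#' @param read_length Read length in bp; must not exceed either sequence.
#' @param error_rate Per-base substitution error probability.
#' @param seed Optional integer seed.
#' @return An object of class `mt_readset`: list with `reads` (character
#'   vector), `ids`, `read_length` and `source_labels` ("major"/"minor").
#' @export
simulate_mixture_reads <- function(major, minor, minor_fraction, depth,
                                   read_length, error_rate = 0, seed = NULL) {
  if (minor_fraction < 0 || minor_fraction > 1)
    stop("minor_fraction must be in [0, 1]")
  if (read_length > nchar(major) || read_length > nchar(minor))
    stop("read_length exceeds sequence length")
  if (!is.null(seed)) set.seed(seed)
  n_reads <- max(1L, as.integer(round(depth * nchar(major) / read_length)))
  from_minor <- stats::runif(n_reads) < minor_fraction
  srcs <- ifelse(from_minor, "minor", "major")
  dbl_major <- paste0(major, major)
  dbl_minor <- paste0(minor, minor)
  len_major <- nchar(major); len_minor <- nchar(minor)
  starts <- integer(n_reads)
  starts[!from_minor] <- sample.int(len_major, sum(!from_minor), replace = TRUE)
  starts[from_minor] <- sample.int(len_minor, sum(from_minor), replace = TRUE)
  src_dbl <- ifelse(from_minor, dbl_minor, dbl_major)
  reads <- substr(src_dbl, starts, starts + read_length - 1L)
  if (error_rate > 0) {
    n_err <- stats::rbinom(1L, n_reads * read_length, error_rate)
    if (n_err > 0L) {
      at <- sample.int(n_reads * read_length, n_err)
      ri <- (at - 1L) %/% read_length + 1L
      pi <- (at - 1L) %% read_length + 1L
      for (e in seq_len(n_err)) {
        cur <- substr(reads[ri[e]], pi[e], pi[e])
        substr(reads[ri[e]], pi[e], pi[e]) <-
          sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
  }
  structure(list(reads = reads,
                 ids = sprintf("read%06d", seq_len(n_reads)),
                 read_length = as.integer(read_length),
                 source_labels = srcs),
            class = "mt_readset")
}

#' Apply a structural variant to a sequence
#'
#' Inserts a payload at, or deletes a fixed length from, a 0-based position.
#' Useful for emulating the multi-kbp indels observed among natural
#' mitogenome assemblies.
#'
#' @param seq A nucleotide sequence (single string).
#' @param kind `"insertion"` or `"deletion"`.
#' @param position 0-based position at which the edit starts.
#' @param payload_or_length The inserted string (insertion) or the number of
#'   deleted bases (deletion).
#' @return The edited sequence.
#' @export
apply_structural_variant <- function(seq, kind = c("insertion", "deletion"),
                                     position, payload_or_length) {
  kind <- match.arg(kind)
  L <- nchar(seq)
  if (position < 0 || position > L) stop("position out of range")
  if (kind == "insertion") {
    payload <- as.character(payload_or_length)
    paste0(substr(seq, 1L, position), payload, substr(seq, position + 1L, L))
  } else {
    len <- as.integer(payload_or_length)
    if (len < 0 || position + len > L) stop("deletion exceeds sequence")
    paste0(substr(seq, 1L, position), substr(seq, position + len + 1L, L))
  }
}

#' Write a read set to FASTQ
#'
#' Writes reads with a constant dummy quality string ("I"). A sidecar TSV of
#' truth labels can be written alongside.
#'
#' @param rs An `mt_readset`.
#' @param path Output FASTQ path.
#' @param truth_path Optional path for a two-column TSV (id, source).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path, truth_path = NULL) {
  stopifnot(inherits(rs, "mt_readset"))
  qual <- strrep("I", rs$read_length)
  out <- character(4L * length(rs$reads))
  out[seq(1L, length(out), 4L)] <- paste0("@", rs$ids)
  out[seq(2L, length(out), 4L)] <- rs$reads
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- qual
  writeLines(out, path)
  if (!is.null(truth_path))
    utils::write.table(data.frame(id = rs$ids, source = rs$source_labels),
                       truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
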