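#' Alignment container
#'
#' A thin S3 container for a gapped multi-sequence alignment: a character
#' matrix (one row per sample, one single-character column per alignment
#' column) over the alphabet `A C G T - N`, with a circularity flag.
#' Coordinates are 0-based half-open everywhere in this package; 1-based
#' positions appear only in rendered reports.
#'
#' @param x Character matrix of single characters, or a character vector of
#'   equal-length sequences.
#' @param sample_ids Unique sample identifiers (row names).
#' @param circular Logical circularity flag.
#' @param coordinate_origin 0-based column index treated as the origin.
#' @return An object of class `mt_alignment`.
#' @export
mt_alignment <- function(x, sample_ids = NULL, circular = TRUE,
                         coordinate_origin = 0L) {
  if (is.character(x) && is.null(dim(x))) {
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) stop("sequences have unequal lengths")
    x <- do.call(rbind, strsplit(toupper(x), ""))
  }
  stopifnot(is.matrix(x))
  x[] <- toupper(x)
  x[x == "U"] <- "T"
  if (is.null(sample_ids)) sample_ids <- rownames(x)
  if (is.null(sample_ids)) sample_ids <- sprintf("seq%02d", seq_len(nrow(x)))
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  rownames(x) <- sample_ids
  structure(x, class = c("mt_alignment", class(x)),
            circular = isTRUE(circular),
            coordinate_origin = as.integer(coordinate_origin))
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat(sprintf("mt_alignment: %d sequences x %d columns (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "circular"))) "circular" else "linear"))
  invisible(x)
}

#' Number of samples and columns of an alignment
#' @param aln An `mt_alignment`.
#' @return Integer count.
#' @export
n_sequences <- function(aln) nrow(aln)

#' Sequences of an alignment as strings
#' @param aln An `mt_alignment`.
#' @return Named character vector of (gapped) sequences.
#' @export
alignment_strings <- function(aln) {
  out <- apply(unclass(aln), 1L, paste, collapse = "")
  names(out) <- rownames(aln)
  out
}

#' Load a FASTA alignment
#'
#' Reads an aligned FASTA file into an [mt_alignment]: record order is
#' preserved, sequences are uppercased and U is converted to T. Ragged
#' record lengths or an empty file are format errors.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical; declare the alignment circular.
#' @return An `mt_alignment`.
#' @export
load_alignment <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 1L) stop("format error: empty FASTA")
  lens <- Biostrings::width(ss)
  if (length(unique(lens)) != 1L)
    stop("format error: ragged sequence lengths (", paste(unique(lens), collapse = ", "), ")")
  ids <- sub("\\s.*$", "", names(ss))
  mt_alignment(as.character(ss), sample_ids = ids, circular = circular)
}

#' Write an alignment to FASTA
#' @param aln An `mt_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  seqs <- alignment_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(seqs[[i]], con)
  }
  invisible(path)
}

.revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Reverse complement of a nucleotide string
#' @param s Character vector of sequences.
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(s) .revcomp(s)

#' Rotate a circular assembly to match a reference start
#'
#' Circular assemblies start at arbitrary points. This finds the best
#' occurrence of the first `anchor_length` bases of `ref` in `seq` (treated
#' as circular), on either strand, and returns `seq` rotated (and
#' reverse-complemented if the anchor matched the reverse strand) so that it
#' begins at the matched locus. Exact matches are preferred; otherwise the
#' highest-identity offset is used, provided identity reaches
#' `min_identity`.
#'
#' @param seq Assembly to rotate (single ungapped string).
#' @param ref Reference sequence providing the anchor.
#' @param anchor_length Anchor length in bp (default 500, capped at the
#'   sequence length).
#' @param min_identity Minimum anchor identity for the fallback search.
#' @return The rotated sequence (same length as `seq`).
#' @export
rotate_to_reference <- function(seq, ref, anchor_length = 500L,
                                min_identity = 0.8) {
  L <- nchar(seq)
  anchor_length <- min(as.integer(anchor_length), L, nchar(ref))
  anchor <- substr(ref, 1L, anchor_length)
  for (strand in c("fwd", "rev")) {
    s <- if (strand == "fwd") seq else .revcomp(seq)
    dbl <- paste0(s, s)
    hit <- regexpr(anchor, substr(dbl, 1L, L + anchor_length - 1L), fixed = TRUE)
    if (hit > 0L) {
      off <- as.integer(hit) - 1L
      return(substr(paste0(s, s), off + 1L, off + L))
    }
  }
  # fallback: best-identity offset on either strand
  best <- list(ident = -1, seq = NULL)
  a_chars <- strsplit(anchor, "")[[1]]
  for (strand in c("fwd", "rev")) {
    s <- if (strand == "fwd") seq else .revcomp(seq)
    dbl_chars <- strsplit(paste0(s, s), "")[[1]]
    for (off in 0:(L - 1L)) {
      ident <- sum(dbl_chars[(off + 1L):(off + anchor_length)] == a_chars) /
        anchor_length
      if (ident > best$ident)
        best <- list(ident = ident,
                     seq = paste(dbl_chars[(off + 1L):(off + L)], collapse = ""))
    }
  }
  if (best$ident < min_identity)
    stop(sprintf("rotation error: best anchor identity %.3f < %.3f",
                 best$ident, min_identity))
  best$seq
}

#' GC content of a sequence
#'
#' Fraction of unambiguous bases that are G or C; gaps and Ns are excluded
#' from the denominator.
#'
#' @param seq A nucleotide string (or vector of strings, concatenated).
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  ch <- strsplit(toupper(paste(seq, collapse = "")), "")[[1]]
  gc <- sum(ch %in% c("G", "C"))
  at <- sum(ch %in% c("A", "T"))
  if (gc + at == 0L) stop("no unambiguous bases")
  gc / (gc + at)
}
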