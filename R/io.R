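# plain-text serializers for the package's tabular objects; all coordinates
# written 0-based half-open except the VCF body (1-based, per that format)

#' Write a site table as TSV
#' @param sites An `mt_sites`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  df <- sites$sites
  geno <- sites$geno
  df$alleles <- apply(geno, 2L, function(g)
    paste(ifelse(is.na(g), ".", g), collapse = ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write biallelic sites as a minimal VCF
#'
#' Four-column body (CHROM, POS, REF = major allele, ALT = minor allele)
#' with a minimal header; positions are 1-based as the format requires.
#'
#' @param sites An `mt_sites`.
#' @param path Output path.
#' @param chrom Chromosome label (default "mt").
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(sites, path, chrom = "mt") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chrom,
                       sites$alignment_length),
               "#CHROM\tPOS\tREF\tALT"), con)
  if (nrow(sites$sites))
    writeLines(sprintf("%s\t%d\t%s\t%s", chrom, sites$sites$pos + 1L,
                       sites$sites$major, sites$sites$minor), con)
  invisible(path)
}

#' Write haplotype blocks as BED-like TSV
#' @param blocks Data.frame from [haplotype_blocks()].
#' @param path Output path.
#' @param chrom Chromosome label.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path, chrom = "mt") {
  utils::write.table(data.frame(chrom = chrom, start = blocks$start_column,
                                end = blocks$end_column),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Serialize a two-locus lookup table
#'
#' Writes the log-likelihood matrix as TSV (rows: canonical configurations)
#' and a JSON sidecar with the metadata (n, theta, grid, seed).
#'
#' @param table An `mt_lookup`.
#' @param path TSV path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_lookup_table <- function(table, path) {
  df <- data.frame(config = rownames(table$loglik), table$loglik,
                   check.names = FALSE)
  names(df)[-1L] <- sprintf("C_%g", table$rho_grid)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(n = table$n, theta_site = table$theta_site,
               rho_grid = table$rho_grid, n_sims = table$n_sims,
               seed = table$seed, floor_log = table$floor_log)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a serialized lookup table
#' @param path TSV path written by [write_lookup_table()].
#' @return An `mt_lookup`.
#' @export
read_lookup_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  ll <- as.matrix(df[, -1L, drop = FALSE])
  rownames(ll) <- df$config
  colnames(ll) <- NULL
  structure(list(n = as.integer(meta$n), theta_site = meta$theta_site,
                 rho_grid = meta$rho_grid, loglik = ll,
                 floor_log = meta$floor_log,
                 n_sims = as.integer(meta$n_sims), seed = meta$seed),
            class = "mt_lookup")
}

#' Write a variable-rho map as TSV
#' @param map An `mt_rhomap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rhomap_tsv <- function(map, path) {
  utils::write.table(map$windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a k-mer library (sorted plain-text list + JSON sidecar)
#' @param lib An `mt_kmerlib`.
#' @param path Output path for the k-mer list.
#' @return `path`, invisibly.
#' @export
write_kmer_library <- function(lib, path) {
  writeLines(lib$kmers, path)
  jsonlite::write_json(list(type_x = lib$type_x_id, type_y = lib$type_y_id,
                            k = lib$k, min_diff = lib$min_diff,
                            size = lib$size),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ path (uncompressed).
#' @return An `mt_readset` (source labels NULL).
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4L != 0L) stop("format error: truncated FASTQ")
  reads <- toupper(ln[seq(2L, length(ln), 4L)])
  ids <- sub("^@", "", sub("\\s.*$", "", ln[seq(1L, length(ln), 4L)]))
  lens <- unique(nchar(reads))
  structure(list(reads = reads, ids = ids,
                 read_length = if (length(lens) == 1L) lens else NA_integer_,
                 source_labels = NULL),
            class = "mt_readset")
}
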