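#' Read a run configuration file
#'
#' Flat key-value text with `[section]` headers, `key = value` lines and
#' `#` comments. Values are split on commas where a list is expected.
#' Unknown keys are kept verbatim so configs round-trip.
#'
#' @param path Config file path.
#' @return Nested named list of class `mt_config` (sections of key-value
#'   character entries).
#' @export
read_run_config <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  cfg <- list()
  section <- "global"
  for (l in ln) {
    if (grepl("^\\[.*\\]$", l)) {
      section <- gsub("^\\[|\\]$", "", l)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", l, fixed = TRUE)) {
      kv <- strsplit(l, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      cfg[[section]][[key]] <- trimws(paste(kv[-1L], collapse = "="))
    }
  }
  structure(cfg, class = "mt_config")
}

.cfg_get <- function(cfg, section, key, default = NULL) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}
.cfg_num <- function(cfg, section, key, default) {
  as.numeric(.cfg_get(cfg, section, key, default))
}
.cfg_nums <- function(cfg, section, key, default) {
  v <- .cfg_get(cfg, section, key, NULL)
  if (is.null(v)) default else as.numeric(strsplit(v, ",")[[1L]])
}

# stage sub-seeds are derived from the base seed so every random stage is
# independently reproducible; kept below 2^31
.stage_seed <- function(seed, stage) (seed * 1009L + stage) %% 2147483647L

.log_line <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full recombination analysis suite
#'
#' Executes, from one config, the package's recombination battery on an
#' alignment: four-gamete scan and haplotype blocks, Mantel LD-decay tests
#' (both statistics, both chunk sizes), maximum chi-square (whole alignment
#' and optional subregion), PHI, and constant plus variable composite
#' likelihood rho estimation. Failures in one stage are logged and marked;
#' the other stages proceed. All result tables are written as TSV under the
#' config's output directory together with a Table-style plain-text summary
#' and the archived config (whose MD5 hash stamps every table).
#'
#' @param config An `mt_config`, a path to one, or a list; see the config
#'   template in the package vignette. When `config$input$alignment_object`
#'   holds an [mt_alignment] (programmatic use) no file is read.
#' @return List of class `mt_report` with per-stage results, `failed`
#'   (character vector of failed stages) and `summary_path`.
#' @export
run_recombination_suite <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- .cfg_get(config, "output", "dir", tempfile("mitorec_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(.cfg_num(config, "params", "seed", 1))
  n_perm <- as.integer(.cfg_num(config, "params", "n_perm", 199))
  chunk_sizes <- .cfg_nums(config, "params", "chunk_sizes", c(10000, 20000))
  region <- .cfg_nums(config, "params", "region", NULL)
  wfrac <- .cfg_num(config, "params", "window_fraction", 2 / 3)
  phi_window <- .cfg_num(config, "params", "phi_window", 100)
  mmc <- as.integer(.cfg_num(config, "params", "min_minor_count", 1))
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))

  aln <- config$input$alignment_object
  if (is.null(aln)) {
    path <- .cfg_get(config, "input", "alignment")
    if (is.null(path)) stop("config: input alignment missing")
    circ <- tolower(.cfg_get(config, "input", "circular", "true")) == "true"
    aln <- load_alignment(path, circular = circ)
  }
  cfg_path <- file.path(out_dir, "config_used.txt")
  .write_config(config, cfg_path)
  cfg_hash <- .config_hash(config)
  stamp <- function(path) {
    cat(sprintf("# config_md5: %s\n", cfg_hash), file = path, append = TRUE)
  }
  results <- list(); failed <- character(0)
  stage_i <- 0L
  run_stage <- function(name, fun) {
    stage_i <<- stage_i + 1L
    set.seed(.stage_seed(seed, stage_i))
    .log_line(log_con, name, sprintf("start (sub-seed %d)",
                                     .stage_seed(seed, stage_i)))
    res <- tryCatch(fun(), error = function(e) {
      .log_line(log_con, name, paste("FAILED:", conditionMessage(e)))
      failed <<- c(failed, name)
      NULL
    })
    if (!is.null(res)) .log_line(log_con, name, "done")
    results[[name]] <<- res
    res
  }

  sites <- run_stage("sites", function() {
    s <- extract_biallelic_sites(aln, min_minor_count = mmc)
    p <- file.path(out_dir, "sites.tsv"); write_sites_tsv(s, p); stamp(p)
    s
  })
  run_stage("four_gamete", function() {
    fg <- four_gamete_scan(sites, return_pairs = FALSE)
    bl <- haplotype_blocks(sites)
    p <- file.path(out_dir, "blocks.bed"); write_blocks_bed(bl, p); stamp(p)
    list(n_violating = fg$n_violating, n_pairs = fg$n_pairs, blocks = bl)
  })
  for (cs in chunk_sizes) for (st in c("r2", "Dprime")) {
    local({
      cs_ <- cs; st_ <- st
      run_stage(sprintf("mantel_%s_%d", st_, cs_), function() {
        mt <- ld_distance_mantel(aln, chunk_size = cs_, stat = st_,
                                 min_minor_count = mmc, n_perm = n_perm)
        p <- file.path(out_dir, sprintf("mantel_%s_%d.tsv", st_, cs_))
        utils::write.table(mt, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        stamp(p)
        mt
      })
    })
  }
  run_stage("maxchi_whole", function()
    max_chi2_test(aln, window_fraction = wfrac, n_perm = n_perm,
                  min_minor_count = mmc))
  if (!is.null(region)) {
    run_stage("maxchi_region", function()
      max_chi2_test(aln, window_fraction = wfrac, n_perm = n_perm,
                    region = region, min_minor_count = mmc))
    run_stage("phi_region", function()
      phi_test(aln, window = phi_window, n_perm = n_perm, region = region))
  } else {
    run_stage("phi", function()
      phi_test(aln, window = phi_window, n_perm = n_perm))
  }
  run_stage("rho", function() {
    tab <- build_two_locus_table(
      n = nrow(aln),
      theta_site = .cfg_num(config, "params", "theta_site", 0.003),
      rho_grid = c(0, exp(seq(log(0.1),
                              log(.cfg_num(config, "params", "rho_grid_max", 100)),
                              length.out = as.integer(
                                .cfg_num(config, "params", "rho_grid_points", 21)) - 1L))),
      n_sims = as.integer(.cfg_num(config, "params", "lookup_n_sims", 400)),
      seed = .stage_seed(seed, 97L))
    cst <- estimate_constant_rho(sites, tab)
    map <- estimate_variable_rho(
      sites, tab,
      block_penalty = .cfg_num(config, "params", "block_penalty", 5),
      n_iter = as.integer(.cfg_num(config, "params", "interval_iters", 20000)),
      thin = as.integer(.cfg_num(config, "params", "interval_thin", 200)),
      window = as.integer(.cfg_num(config, "params", "map_window", 2000)),
      seed = .stage_seed(seed, 98L))
    p <- file.path(out_dir, "rho_map.tsv"); write_rhomap_tsv(map, p); stamp(p)
    list(constant = cst, map = map)
  })

  summary_path <- file.path(out_dir, "summary.txt")
  .write_recomb_summary(results, failed, cfg_hash, summary_path)
  structure(list(results = results, failed = failed,
                 summary_path = summary_path, out_dir = out_dir,
                 config_md5 = cfg_hash),
            class = "mt_report")
}


# config hash over input + params only (output paths differ between
# otherwise-identical runs and must not change the stamp)
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg2 <- cfg[setdiff(names(cfg), "output")]
  .write_config(cfg2, tmp)
  unname(tools::md5sum(tmp))
}

.write_config <- function(cfg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sec in names(cfg)) {
    entries <- cfg[[sec]]
    if (!is.list(entries)) next
    writeLines(sprintf("[%s]", sec), con)
    for (key in names(entries)) {
      v <- entries[[key]]
      if ((is.character(v) || is.numeric(v)) && is.null(dim(v)) &&
          length(v) <= 8L)
        writeLines(sprintf("%s = %s", key, paste(v, collapse = ",")), con)
    }
  }
  invisible(path)
}

.write_recomb_summary <- function(results, failed, cfg_hash, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# recombination suite summary (config_md5 %s)", cfg_hash)
  fg <- results$four_gamete
  if (!is.null(fg)) {
    w("four-gamete violating pairs\t%d/%d (%.1f%%)", fg$n_violating,
      fg$n_pairs, if (fg$n_pairs > 0) 100 * fg$n_violating / fg$n_pairs else 0)
    w("haplotype blocks\t%d", nrow(fg$blocks))
  }
  for (nm in names(results)) {
    if (grepl("^mantel_", nm) && !is.null(results[[nm]])) {
      mt <- results[[nm]]
      sig <- sum(mt$testable & mt$p_value < 0.05, na.rm = TRUE)
      w("%s\t%d/%d chunks significant", nm, sig, sum(mt$testable))
    }
  }
  for (nm in c("maxchi_whole", "maxchi_region", "phi", "phi_region")) {
    r <- results[[nm]]
    if (!is.null(r)) w("%s\tstatistic %.4g\tp %.4g", nm, r$statistic,
                       r$p_value)
  }
  if (!is.null(results$rho)) {
    w("constant rho per site\t%.4g", results$rho$constant$rho_site)
    w("r/m (rho/theta_w)\t%.4g",
      results$rho$constant$r_over_m$rho_over_theta_w)
    w("r/m (rho/pi)\t%.4g", results$rho$constant$r_over_m$rho_over_pi)
    w("mean map rho per site\t%.4g", results$rho$map$global_mean_rho)
  }
  if (length(failed)) w("FAILED stages\t%s", paste(failed, collapse = ","))
  invisible(path)
}

#' Run the heteroplasmy survey
#'
#' For every sample in the config: reads are classified against all
#' pairwise discriminating k-mer libraries among the candidate mitotypes,
#' heteroplasmy is estimated, right-tail beta outliers are flagged, and the
#' two named groups are compared by a Mann-Whitney test (skipped with a
#' recorded reason when a group has fewer than one sample or only one group
#' exists).
#'
#' @param config An `mt_config` / path / list. Programmatic use: supply
#'   `config$input$assemblies_object` (an [mt_alignment] of mitotype
#'   assemblies) and `config$input$samples_object` (data.frame: `id`,
#'   `reads` (`mt_readset`) or `fastq` path, `group`, `major`).
#' @return List of class `mt_report` with the per-sample table (`H_hat`,
#'   selected candidate, outlier flag), `group_medians`, `mann_whitney`,
#'   `failed` and `summary_path`.
#' @export
run_heteroplasmy_survey <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- .cfg_get(config, "output", "dir", tempfile("mitorec_het"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  k <- as.integer(.cfg_num(config, "params", "k", 251))
  min_diff <- as.integer(.cfg_num(config, "params", "min_diff", 2))
  rho_out <- .cfg_num(config, "params", "outlier_rho", 1)
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))

  asm <- config$input$assemblies_object
  if (is.null(asm)) {
    path <- .cfg_get(config, "input", "assemblies")
    if (is.null(path)) stop("config: assemblies missing")
    asm <- load_alignment(path, circular = TRUE)
  }
  samples <- config$input$samples_object
  if (is.null(samples)) {
    stab <- config$samples
    if (is.null(stab)) stop("config: [samples] section missing")
    samples <- do.call(rbind, lapply(names(stab), function(id) {
      f <- strsplit(stab[[id]], ",")[[1L]]
      data.frame(id = id, fastq = f[1L], group = f[2L], major = f[3L],
                 stringsAsFactors = FALSE)
    }))
  }
  cfg_path <- file.path(out_dir, "config_used.txt")
  .write_config(config, cfg_path)
  cfg_hash <- .config_hash(config)
  failed <- character(0)
  .log_line(log_con, "libraries", "building pairwise k-mer libraries")
  libs <- build_all_kmer_libraries(asm, k = k, min_diff = min_diff)
  cand_all <- rownames(asm)
  res <- data.frame(id = samples$id, group = samples$group,
                    major = samples$major, H_hat = NA_real_,
                    selected = NA_character_, outlier = FALSE,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(samples))) {
    est <- tryCatch({
      reads <- if (!is.null(samples$reads)) samples$reads[[r]] else
        read_fastq(samples$fastq[r])
      estimate_heteroplasmy(reads, samples$major[r],
                            setdiff(cand_all, samples$major[r]), libs)
    }, error = function(e) {
      .log_line(log_con, samples$id[r], paste("FAILED:", conditionMessage(e)))
      failed <<- c(failed, samples$id[r])
      NULL
    })
    if (!is.null(est)) {
      res$H_hat[r] <- est$H_hat
      res$selected[r] <- est$selected_candidate
    }
  }
  ok <- !is.na(res$H_hat)
  outl <- NULL
  if (sum(ok) >= 5L) {
    outl <- tryCatch(beta_outlier_detection(res$H_hat[ok], rho = rho_out),
                     error = function(e) NULL)
    if (!is.null(outl)) res$outlier[ok] <- outl$outlier
  }
  groups <- split(res$H_hat[ok], res$group[ok])
  med <- vapply(groups, stats::median, numeric(1))
  mw <- NULL; mw_skip <- NULL
  if (length(groups) == 2L && all(lengths(groups) >= 1L) &&
      sum(lengths(groups)) >= 3L) {
    mw <- mann_whitney_test(groups[[1L]], groups[[2L]])
  } else {
    mw_skip <- sprintf("Mann-Whitney skipped: %d group(s) with sizes %s",
                       length(groups), paste(lengths(groups), collapse = "/"))
    .log_line(log_con, "mann_whitney", mw_skip)
  }
  tsv <- file.path(out_dir, "heteroplasmy.tsv")
  utils::write.table(res, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# config_md5: %s\n", cfg_hash), file = tsv, append = TRUE)
  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  writeLines(sprintf("# heteroplasmy survey summary (config_md5 %s)", cfg_hash), con)
  for (g in names(med))
    writeLines(sprintf("median H_hat %s\t%.6g", g, med[g]), con)
  if (!is.null(mw))
    writeLines(sprintf("Mann-Whitney U\t%g\tp\t%.4g", mw$statistic,
                       mw$p_value), con)
  if (!is.null(mw_skip)) writeLines(mw_skip, con)
  if (length(failed))
    writeLines(sprintf("FAILED samples\t%s", paste(failed, collapse = ",")), con)
  close(con)
  structure(list(samples = res, group_medians = med, mann_whitney = mw,
                 mann_whitney_skipped = mw_skip, outliers = outl,
                 failed = failed, summary_path = summary_path,
                 out_dir = out_dir, config_md5 = cfg_hash),
            class = "mt_report")
}
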