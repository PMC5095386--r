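#' Write simulator outputs to disk
#'
#' Writes a multi-sample VCF 4.2 (`GT:DP:AD`; positions 1-based, sorted;
#' declared genotypes come from [classify_genotype()] of the simulated
#' allele depths), the truth tables as TSV (`sample chrom gamete pos` for
#' crossover breakpoints, `sample chrom pos near_co` for mutations), and an
#' echo of the configuration as YAML. The simulator assigns constant
#' REF/ALT alleles (A/T): allele identity never enters the analysis, only
#' genotype classes do.
#'
#' @param sim a `sim_result` from [simulate_f2_population()].
#' @param dir output directory (created if absent).
#' @param mutations optional mutation table from [inject_mutations()].
#' @return Invisibly, a named list of the written paths.
#' @export
write_sim_outputs <- function(sim, dir, mutations = NULL) {
  stopifnot(inherits(sim, "sim_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "markers.vcf"),
                breakpoints = file.path(dir, "truth_breakpoints.tsv"),
                mutations = file.path(dir, "truth_mutations.tsv"),
                config = file.path(dir, "sim_config.yaml"))
  write_marker_vcf(sim$records, paths$vcf, sim$config$chrom_lengths)
  utils::write.table(sim$truth$breakpoints, paths$breakpoints, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(mutations))
    utils::write.table(mutations, paths$mutations, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  cfg$marker_density <- as.list(cfg$marker_density)
  cfg$mean_co_per_gamete <- as.list(cfg$mean_co_per_gamete)
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], paths$config)
  invisible(paths)
}

#' Write a `variant_records` object as a multi-sample VCF
#'
#' @param records a `variant_records` object.
#' @param path output path (plain text).
#' @param chrom_lengths optional named vector for `##contig` header lines.
#' @return Invisibly, `path`.
#' @export
write_marker_vcf <- function(records, path, chrom_lengths = NULL) {
  stopifnot(inherits(records, "variant_records"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=coscape",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">'
  ), con)
  if (!is.null(chrom_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                       as.integer(chrom_lengths)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", records$samples), collapse = "\t"),
             con)
  gt_str <- c("0/0", "0/1", "1/1")
  n_m <- nrow(records$sites)
  cols <- vapply(seq_along(records$samples), function(s) {
    code <- classify_genotype_code(records$ad_ref[, s], records$ad_alt[, s],
                                   records$dp[, s])
    gt <- ifelse(is.na(code), "./.", gt_str[code + 1L])
    sprintf("%s:%d:%d,%d", gt, records$dp[, s], records$ad_ref[, s],
            records$ad_alt[, s])
  }, character(n_m))
  body <- paste(records$sites$chrom, records$sites$pos, ".",
                records$sites$ref, records$sites$alt,
                format(records$sites$qual, trim = TRUE), "PASS", ".",
                "GT:DP:AD", sep = "\t")
  writeLines(paste(body, apply(cols, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a multi-sample VCF into a `variant_records` object
#'
#' Thin wrapper around [vcfR::read.vcfR()] extracting `DP` and `AD`
#' per-sample fields. Multi-allelic records are kept but flagged
#' (`biallelic = FALSE`) so that [filter_variants()] can drop them.
#'
#' @param path VCF path (plain or gzipped).
#' @param f1 sample name of the F1 parent.
#' @return A `variant_records` object: `sites` data frame
#'   (`chrom,pos,ref,alt,qual,biallelic`), integer matrices `dp`, `ad_ref`,
#'   `ad_alt` (sites x samples), `samples`, `f1`.
#' @export
read_marker_vcf <- function(path, f1 = "F1") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  samples <- colnames(v@gt)[-1L]
  if (!f1 %in% samples)
    stop("F1 sample '", f1, "' not found in VCF")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  ad_ref <- apply(ad, 2L, function(x)
    as.integer(vapply(strsplit(x, ","), `[`, character(1), 1L)))
  ad_alt <- apply(ad, 2L, function(x)
    as.integer(vapply(strsplit(x, ","), `[`, character(1), 2L)))
  mode(dp) <- "integer"
  dimnames(dp) <- dimnames(ad_ref) <- dimnames(ad_alt) <-
    list(NULL, samples)
  structure(list(
    sites = data.frame(chrom = unname(fix[, "CHROM"]),
                       pos = as.numeric(fix[, "POS"]),
                       ref = unname(fix[, "REF"]),
                       alt = unname(fix[, "ALT"]),
                       qual = as.numeric(fix[, "QUAL"]),
                       biallelic = !grepl(",", fix[, "ALT"]),
                       stringsAsFactors = FALSE),
    dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
    samples = samples, f1 = f1
  ), class = "variant_records")
}

#' Read a chromosome-length table (FASTA-index style)
#'
#' Reads the first two columns (name, length) of a `.fai`-style file.
#'
#' @param path TSV path.
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
read_chrom_lengths <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}

#' Read a BED-like interval table
#'
#' Reads `chrom start end [type caller]` (0-based half-open), e.g.
#' structural-variant calls or peri-centromere annotations.
#'
#' @param path TSV/BED path (no header).
#' @param col_names column names to assign, by position.
#' @return Data frame with the requested columns.
#' @export
read_intervals <- function(path, col_names = c("chrom", "start", "end",
                                               "type", "caller")) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  colnames(tab) <- col_names[seq_len(ncol(tab))]
  tab
}
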