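#' Classify a genotype from allele depths by allele balance
#'
#' Implements the confident-call allele-balance rule: with reference allelic
#' ratio r = ad_ref / (ad_ref + ad_alt), a call is `HOM_REF` when r >= 0.95,
#' `HOM_ALT` when r <= 0.05, `HET` when 0.30 <= r <= 0.70, and `MISSING`
#' otherwise — also `MISSING` whenever the depth lies outside
#' `[min_depth, max_depth]` or no genotyped reads exist. The ratio uses the
#' AD sum; the depth bounds use `depth` (DP), which defaults to the AD sum
#' when the caller supplies none.
#'
#' @param ad_ref,ad_alt non-negative integer vectors of reference/alternate
#'   allele depths.
#' @param depth total read depth; recycled; defaults to `ad_ref + ad_alt`.
#' @param min_depth,max_depth inclusive depth bounds (defaults 10 and 80).
#' @return Character vector with values `HOM_REF`, `HOM_ALT`, `HET`,
#'   `MISSING`.
#' @export
#' @examples
#' classify_genotype(c(50, 25, 10, 30), c(0, 25, 40, 30),
#'                   c(50, 50, 50, 90))
classify_genotype <- function(ad_ref, ad_alt, depth = ad_ref + ad_alt,
                              min_depth = 10, max_depth = 80) {
  geno_code_to_label(classify_genotype_code(ad_ref, ad_alt, depth,
                                            min_depth, max_depth))
}

# integer-coded fast path: 0 HOM_REF, 1 HET, 2 HOM_ALT, NA MISSING
classify_genotype_code <- function(ad_ref, ad_alt,
                                   depth = ad_ref + ad_alt,
                                   min_depth = 10, max_depth = 80) {
  n <- length(ad_ref)
  stopifnot(length(ad_alt) == n)
  depth <- rep_len(depth, n)
  tot <- ad_ref + ad_alt
  code <- rep(NA_integer_, n)
  ok <- !is.na(tot) & !is.na(depth) & tot > 0 &
    depth >= min_depth & depth <= max_depth
  r <- ad_ref[ok] / tot[ok]
  sub <- rep(NA_integer_, sum(ok))
  sub[r >= 0.95] <- 0L
  sub[r <= 0.05] <- 2L
  sub[r >= 0.30 & r <= 0.70] <- 1L
  code[ok] <- sub
  code
}

#' Filter raw variant records to confident F1-heterozygous markers
#'
#' Keeps bi-allelic records with quality >= `qual_min` for which strictly
#' more than half of the samples have an informative (non-`MISSING`) call
#' under [classify_genotype()] and the F1 call is confidently heterozygous.
#' The retained sites and their per-sample calls form the marker matrix all
#' downstream block and crossover calling operates on.
#'
#' @param records a `variant_records` object (see [read_marker_vcf()] or
#'   [simulate_f2_population()]).
#' @param f1 F1 sample name; default taken from the records.
#' @param qual_min minimum variant quality (default 50).
#' @param min_depth,max_depth per-sample depth bounds passed to
#'   [classify_genotype()].
#' @param depth_source `"dp"` (default) applies the depth bounds to the DP
#'   field; `"ad_sum"` applies them to the AD sum.
#' @return A `marker_matrix`: list with `markers` (data frame
#'   `chrom,pos,ref,alt`), `geno` (integer matrix markers x samples, codes
#'   0/1/2/NA), `samples`, `f1`. Attribute `n_input` records the input site
#'   count.
#' @export
filter_variants <- function(records, f1 = records$f1, qual_min = 50,
                            min_depth = 10, max_depth = 80,
                            depth_source = c("dp", "ad_sum")) {
  stopifnot(inherits(records, "variant_records"))
  depth_source <- match.arg(depth_source)
  sites <- records$sites
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("records must be sorted by (chrom, pos)")
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("duplicate (chrom, pos) records")
  if (!f1 %in% records$samples) stop("unknown F1 sample: ", f1)

  n_s <- length(records$samples)
  depth <- if (depth_source == "dp") records$dp else
    records$ad_ref + records$ad_alt
  geno <- matrix(NA_integer_, nrow(sites), n_s,
                 dimnames = list(NULL, records$samples))
  for (s in seq_len(n_s))
    geno[, s] <- classify_genotype_code(records$ad_ref[, s],
                                        records$ad_alt[, s], depth[, s],
                                        min_depth, max_depth)
  informative <- rowSums(!is.na(geno))
  keep <- sites$biallelic & !is.na(sites$qual) & sites$qual >= qual_min &
    informative > n_s / 2 & !is.na(geno[, f1]) & geno[, f1] == 1L
  structure(list(
    markers = sites[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE],
    geno = geno[keep, , drop = FALSE],
    samples = records$samples, f1 = f1
  ), class = "marker_matrix", n_input = nrow(sites))
}

#' Build a structural-variant mask
#'
#' Converts a union set of structural-variant calls into mask intervals for
#' pseudo-heterozygosity removal: SVs spanning < 100 kbp are masked whole
#' (inversions with an extra 200 bp flank on both sides); SVs spanning
#' >= 100 kbp contribute only the 400 bp flanks around each of their two
#' breakpoints. Intervals are merged and sorted; intervals extending beyond
#' a chromosome are clipped with a warning.
#'
#' @param sv_intervals data frame `chrom,start,end,type[,caller]` with
#'   0-based half-open coordinates and type in `DEL`, `DUP`, `INV`, `TRA`.
#' @param chrom_lengths optional named vector used for clipping.
#' @param large_sv_size span threshold in bp (default 1e5).
#' @param inv_flank,breakpoint_flank flank sizes in bp (defaults 200, 400).
#' @return A `GRanges` of merged mask intervals (0-based half-open encoded
#'   as IRanges start = start + 1).
#' @export
build_sv_mask <- function(sv_intervals, chrom_lengths = NULL,
                          large_sv_size = 1e5, inv_flank = 200,
                          breakpoint_flank = 400) {
  stopifnot(all(c("chrom", "start", "end", "type") %in%
                  colnames(sv_intervals)))
  bad <- setdiff(unique(sv_intervals$type), c("DEL", "DUP", "INV", "TRA"))
  if (length(bad)) stop("unknown SV type tag(s): ", paste(bad, collapse = ", "))
  span <- sv_intervals$end - sv_intervals$start
  small <- span < large_sv_size
  pieces <- list()
  if (any(small)) {
    s <- sv_intervals[small, , drop = FALSE]
    flank <- ifelse(s$type == "INV", inv_flank, 0)
    pieces[[1]] <- data.frame(chrom = s$chrom, start = s$start - flank,
                              end = s$end + flank)
  }
  if (any(!small)) {
    l <- sv_intervals[!small, , drop = FALSE]
    pieces[[length(pieces) + 1L]] <- data.frame(
      chrom = rep(l$chrom, 2L),
      start = c(l$start - breakpoint_flank, l$end - breakpoint_flank),
      end = c(l$start + breakpoint_flank, l$end + breakpoint_flank))
  }
  iv <- do.call(rbind, pieces)
  clipped <- FALSE
  if (any(iv$start < 0)) { iv$start[iv$start < 0] <- 0; clipped <- TRUE }
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[iv$chrom]
    over <- !is.na(lim) & iv$end > lim
    if (any(over)) { iv$end[over] <- lim[over]; clipped <- TRUE }
  }
  if (clipped) warning("mask interval(s) clipped to chromosome bounds")
  gr <- GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(start = iv$start + 1, end = iv$end))
  GenomicRanges::reduce(sort(gr))
}

#' Remove markers inside a mask
#'
#' Drops markers of a `marker_matrix` whose position falls in any mask
#' interval. The removed count is reported via attribute `n_masked`.
#'
#' @param matrix_obj a `marker_matrix` from [filter_variants()].
#' @param mask a `GRanges` mask from [build_sv_mask()] (or any intervals).
#' @return The filtered `marker_matrix`.
#' @export
apply_mask <- function(matrix_obj, mask) {
  stopifnot(inherits(matrix_obj, "marker_matrix"))
  if (length(mask) == 0L) {
    attr(matrix_obj, "n_masked") <- 0L
    return(matrix_obj)
  }
  pts <- GenomicRanges::GRanges(
    matrix_obj$markers$chrom,
    IRanges::IRanges(matrix_obj$markers$pos, width = 1L))
  hit <- IRanges::overlapsAny(pts, mask)
  matrix_obj$markers <- matrix_obj$markers[!hit, , drop = FALSE]
  matrix_obj$geno <- matrix_obj$geno[!hit, , drop = FALSE]
  attr(matrix_obj, "n_masked") <- sum(hit)
  matrix_obj
}

#' Flag artefactual marker clustering by the SE of adjacent-marker gaps
#'
#' Over sliding runs of `window_k` markers on each chromosome, computes the
#' standard error of the distances between adjacent markers,
#' SE = sd(gaps) / sqrt(n_gaps), and flags runs with SE strictly greater
#' than `se_threshold` (default 100 bp). Flags are advisory diagnostics of
#' non-proper mapping; nothing is removed automatically.
#'
#' @param matrix_obj a `marker_matrix`.
#' @param window_k run length in markers (default 25, the seed size).
#' @param se_threshold SE threshold in bp (strict `>`, default 100).
#' @return Data frame `chrom, first_idx, last_idx, start, end, se, flagged`
#'   with one row per sliding run.
#' @export
flag_marker_clusters <- function(matrix_obj, window_k = 25,
                                 se_threshold = 100) {
  stopifnot(inherits(matrix_obj, "marker_matrix"), window_k >= 2)
  res <- lapply(unique(matrix_obj$markers$chrom), function(cn) {
    pos <- matrix_obj$markers$pos[matrix_obj$markers$chrom == cn]
    if (length(pos) < window_k) return(NULL)
    gaps <- diff(pos)
    ng <- window_k - 1L
    n_runs <- length(gaps) - ng + 1L
    # rolling sd over windows of ng gaps via cumulative sums
    cs <- c(0, cumsum(gaps))
    cs2 <- c(0, cumsum(gaps^2))
    i <- seq_len(n_runs)
    s <- cs[i + ng] - cs[i]
    s2 <- cs2[i + ng] - cs2[i]
    v <- pmax(0, (s2 - s^2 / ng) / (ng - 1L))
    se <- sqrt(v) / sqrt(ng)
    data.frame(chrom = cn, first_idx = i, last_idx = i + ng,
               start = pos[i], end = pos[i + ng], se = se,
               flagged = se > se_threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
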