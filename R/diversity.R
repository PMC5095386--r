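#' Build a population genotype matrix
#'
#' Container for n individuals x m bi-allelic sites used by the windowed
#' pairwise-diversity statistic. Genotypes are coded 0 (HOM_REF), 1 (HET),
#' 2 (HOM_ALT), `NA` (missing).
#'
#' @param sites data frame `chrom, pos` (1-based, sorted within chrom).
#' @param geno integer matrix sites x individuals with codes 0/1/2/NA.
#' @return A `population_matrix` object.
#' @export
population_matrix <- function(sites, geno) {
  stopifnot(nrow(sites) == nrow(geno),
            all(geno %in% c(0L, 1L, 2L) | is.na(geno)))
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  structure(list(sites = sites[ord, , drop = FALSE],
                 geno = geno[ord, , drop = FALSE]),
            class = "population_matrix")
}

#' Filter population sites by missingness and minor-allele count
#'
#' Drops sites with more than half missing alleles (each missing individual
#' contributes two missing alleles out of 2n) or with a non-reference
#' allele count below `min_alt_count` (default 7, i.e. ~5% of 140 alleles
#' in a 70-individual panel), to reduce false positive calls.
#'
#' @param pop a `population_matrix`.
#' @param min_alt_count minimum alternate allele count (kept when >= this;
#'   default 7).
#' @param max_missing_frac maximum fraction of missing alleles, strict
#'   (default 0.5).
#' @return The filtered `population_matrix`; attribute `n_dropped`.
#' @export
site_filter <- function(pop, min_alt_count = 7, max_missing_frac = 0.5) {
  stopifnot(inherits(pop, "population_matrix"))
  n <- ncol(pop$geno)
  missing_frac <- rowSums(is.na(pop$geno)) / n
  alt_count <- rowSums(pop$geno, na.rm = TRUE)
  keep <- missing_frac <= max_missing_frac & alt_count >= min_alt_count
  out <- structure(list(sites = pop$sites[keep, , drop = FALSE],
                        geno = pop$geno[keep, , drop = FALSE]),
                   class = "population_matrix")
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Per-site pairwise genotype difference
#'
#' The per-site nucleotide difference between two diploid genotypes at a
#' bi-allelic site: 1 between opposite homozygotes, 0.5 between a
#' homozygote and a heterozygote, 0 between identical genotypes, `NA` when
#' either is missing (the site is uninformative for the pair).
#'
#' @param g1,g2 genotype codes (0/1/2/NA), vectorised.
#' @return Numeric vector in \{0, 0.5, 1, NA\}.
#' @export
pairwise_site_diff <- function(g1, g2) {
  abs(g1 - g2) / 2
}

#' Windowed population pairwise diversity
#'
#' For each fixed window and each pair of individuals, sums the per-site
#' differences over sites genotyped in both and divides by the number of
#' such informative sites; the pair contributes only if strictly more than
#' `min_site_frac` of the window's sites are informative for it. The
#' window diversity is the mean over contributing pairs, and the window is
#' retained only when the number of informative pairs reaches
#' `ceiling(min_pair_frac * n_pairs)` (1208 of 2415 for 70 individuals at
#' the defaults).
#'
#' @param pop a `population_matrix` (after [site_filter()]).
#' @param window_size window size in bp (default 500 kbp).
#' @param min_site_frac minimum informative-site fraction per pair, strict
#'   (default 0.5).
#' @param min_pair_frac minimum informative-pair fraction per window
#'   (default 0.5).
#' @param chrom_lengths optional named vector; when given, windows without
#'   sites are emitted as non-retained rows.
#' @return Data frame `chrom, win, start, end, mean_pairwise_diff,
#'   n_informative_pairs, n_sites, retained`.
#' @export
window_diversity <- function(pop, window_size = 5e5, min_site_frac = 0.5,
                             min_pair_frac = 0.5, chrom_lengths = NULL) {
  stopifnot(inherits(pop, "population_matrix"), window_size > 0,
            min_site_frac > 0, min_site_frac <= 1,
            min_pair_frac > 0, min_pair_frac <= 1)
  n <- ncol(pop$geno)
  pairs <- utils::combn(n, 2L)
  n_pairs <- ncol(pairs)
  pair_threshold <- ceiling(min_pair_frac * n_pairs)
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    unique(pop$sites$chrom)
  out <- list()
  for (cn in chroms) {
    idx <- which(pop$sites$chrom == cn)
    win_of <- floor(pop$sites$pos[idx] / window_size)
    n_win <- if (!is.null(chrom_lengths))
      ceiling(chrom_lengths[[cn]] / window_size) else
        if (length(idx)) max(win_of) + 1L else 0L
    if (!is.null(chrom_lengths))
      win_of <- pmin(win_of, n_win - 1L)
    for (w in seq_len(n_win) - 1L) {
      rows <- idx[win_of == w]
      s <- length(rows)
      if (s == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn, win = w, start = w * window_size,
          end = (w + 1) * window_size, mean_pairwise_diff = NA_real_,
          n_informative_pairs = 0L, n_sites = 0L, retained = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      g <- pop$geno[rows, , drop = FALSE]
      pd <- numeric(n_pairs)
      informative <- logical(n_pairs)
      for (k in seq_len(n_pairs)) {
        gi <- g[, pairs[1L, k]]
        gj <- g[, pairs[2L, k]]
        ok <- !is.na(gi) & !is.na(gj)
        n_ok <- sum(ok)
        if (n_ok / s > min_site_frac) {
          informative[k] <- TRUE
          pd[k] <- sum(pairwise_site_diff(gi[ok], gj[ok])) / n_ok
        }
      }
      n_inf <- sum(informative)
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, win = w, start = w * window_size,
        end = (w + 1) * window_size,
        mean_pairwise_diff = if (n_inf) mean(pd[informative]) else NA_real_,
        n_informative_pairs = n_inf, n_sites = s,
        retained = n_inf >= pair_threshold, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Correlation between windowed diversity and crossover counts
#'
#' Joins retained diversity windows to crossover window counts on
#' (chromosome, window) and reports the Spearman correlation.
#'
#' @param div_windows data frame from [window_diversity()].
#' @param co_windows data frame from [window_counts()] at the same window
#'   size.
#' @return List as [spearman_test()], plus `n_windows`.
#' @export
diversity_co_correlation <- function(div_windows, co_windows) {
  dv <- div_windows[div_windows$retained, , drop = FALSE]
  m <- merge(dv[, c("chrom", "win", "mean_pairwise_diff")],
             co_windows[, c("chrom", "win", "co_count")],
             by = c("chrom", "win"))
  if (nrow(m) == 0L) stop("no overlapping windows between the two inputs")
  st <- spearman_test(m$mean_pairwise_diff, m$co_count)
  st$n_windows <- nrow(m)
  st
}
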