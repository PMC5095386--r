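#' Distance from each de novo mutation to the nearest crossover
#'
#' For every mutation, the distance to the nearest crossover midpoint on
#' the same chromosome, either within the same sample's events
#' (`same_sample`, the default: mutagenic recombination acts within a
#' genome) or pooled over all samples (`pooled`). Mutations on a
#' chromosome without eligible events get `Inf` and are excluded from the
#' radius summary.
#'
#' @param mutations data frame `sample, chrom, pos`.
#' @param events events data frame (columns `sample, chrom, midpoint`).
#' @param mode `"same_sample"` or `"pooled"`.
#' @param radii radii (bp) for the within-distance summary (defaults 2 kbp,
#'   10 kbp, 100 kbp).
#' @return The mutations data frame with a `distance` column; attribute
#'   `within_radii` holds the named counts of finite distances <= each
#'   radius.
#' @export
nearest_co_distance <- function(mutations, events,
                                mode = c("same_sample", "pooled"),
                                radii = c(2e3, 1e4, 1e5)) {
  mode <- match.arg(mode)
  if (mode == "same_sample") {
    unknown <- setdiff(unique(mutations$sample), unique(events$sample))
    if (length(unknown))
      stop("mutation sample(s) without any crossover events: ",
           paste(unknown, collapse = ", "))
    key_m <- paste(mutations$sample, mutations$chrom)
    key_e <- paste(events$sample, events$chrom)
  } else {
    key_m <- mutations$chrom
    key_e <- events$chrom
  }
  d <- rep(Inf, nrow(mutations))
  for (k in unique(key_m)) {
    mids <- sort(events$midpoint[key_e == k])
    if (!length(mids)) next
    sel <- which(key_m == k)
    d[sel] <- dist_to_sorted(mutations$pos[sel], mids)
  }
  mutations$distance <- d
  attr(mutations, "within_radii") <-
    stats::setNames(vapply(radii, function(r) sum(d <= r & is.finite(d)),
                           numeric(1)),
                    paste0("within_", radii))
  mutations
}

# distance from each position to the nearest value of a sorted vector
dist_to_sorted <- function(p, mids) {
  n <- length(mids)
  i <- findInterval(p, mids)
  left <- ifelse(i >= 1L, p - mids[pmax(i, 1L)], Inf)
  right <- ifelse(i < n, mids[pmin(i + 1L, n)] - p, Inf)
  pmin(abs(left), abs(right))
}

#' Permutation test for mutation enrichment near crossovers
#'
#' Formalises the descriptive mutation-proximity comparison as a one-sided
#' permutation test: the observed statistic is the number of mutations
#' within `radius` bp of a crossover midpoint; the null re-places each
#' mutation uniformly on its own chromosome (keeping its sample) `n_rand`
#' times. p = (1 + #\{rand >= obs\}) / (1 + n_rand).
#'
#' @param mutations data frame `sample, chrom, pos`.
#' @param events events data frame (`sample, chrom, midpoint`).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param radius proximity radius in bp (default 2 kbp).
#' @param n_rand number of randomizations (default 1000).
#' @param seed optional RNG seed.
#' @param mode see [nearest_co_distance()].
#' @return List `observed, expected, p, n_rand, flagged` (`flagged` with
#'   `p = NA` when there are no mutations).
#' @export
proximity_enrichment_test <- function(mutations, events, chrom_lengths,
                                      radius = 2000, n_rand = 1000,
                                      seed = NULL,
                                      mode = c("same_sample", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(n_rand >= 1)
  if (nrow(mutations) == 0L)
    return(list(observed = NA_integer_, expected = NA_real_, p = NA_real_,
                n_rand = n_rand, flagged = TRUE))
  if (!is.null(seed)) withr::local_seed(seed)
  d_obs <- nearest_co_distance(mutations, events, mode = mode,
                               radii = radius)
  obs <- sum(d_obs$distance <= radius & is.finite(d_obs$distance))
  # null: re-place each mutation uniformly on its own chromosome; grouped
  # by (sample,) chromosome so each group shares one sorted midpoint set
  if (mode == "same_sample") {
    key_m <- paste(mutations$sample, mutations$chrom)
    key_e <- paste(events$sample, events$chrom)
  } else {
    key_m <- mutations$chrom
    key_e <- events$chrom
  }
  null_counts <- numeric(n_rand)
  for (k in unique(key_m)) {
    sel <- which(key_m == k)
    mids <- sort(events$midpoint[key_e == k])
    if (!length(mids)) next
    len <- chrom_lengths[[mutations$chrom[sel[1L]]]]
    draws <- floor(stats::runif(length(sel) * n_rand, 0, len)) + 1
    within <- dist_to_sorted(draws, mids) <= radius
    null_counts <- null_counts +
      colSums(matrix(within, ncol = n_rand))
  }
  list(observed = obs, expected = mean(null_counts),
       p = (1 + sum(null_counts >= obs)) / (1 + n_rand),
       n_rand = n_rand, flagged = FALSE)
}

#' Binned correlation between crossover and mutation counts
#'
#' Bins the genome at each requested size, counts crossover midpoints and
#' mutations per bin, discards bins overlapping peri-centromeric regions
#' (recombination is suppressed there), and reports the Spearman
#' correlation per bin size.
#'
#' @param mutations data frame `sample, chrom, pos`.
#' @param events events data frame (`chrom, midpoint`).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bin_sizes bin sizes in bp (defaults 0.5, 1, 2, 5 Mbp).
#' @param pericentromere optional data frame `chrom,start,end` of bins to
#'   exclude.
#' @return Data frame `bin_size, n_bins, rho, p, flagged`.
#' @export
binned_correlation <- function(mutations, events, chrom_lengths,
                               bin_sizes = c(5e5, 1e6, 2e6, 5e6),
                               pericentromere = NULL) {
  stopifnot(length(bin_sizes) > 0)
  rows <- lapply(bin_sizes, function(size) {
    co <- window_counts(events, chrom_lengths, size)
    mu <- window_counts(mutations, chrom_lengths, size, pos_col = "pos")
    if (!is.null(pericentromere)) {
      co <- telomere_centromere_filter(co, pericentromere = pericentromere,
                                       drop_telomeres = FALSE)
      mu <- telomere_centromere_filter(mu, pericentromere = pericentromere,
                                       drop_telomeres = FALSE)
    }
    if (nrow(co) == 0L) stop("all bins discarded at size ", size)
    if (nrow(mutations) == 0L || sum(mu$co_count) == 0L)
      return(data.frame(bin_size = size, n_bins = nrow(co),
                        rho = NA_real_, p = NA_real_, flagged = TRUE))
    st <- spearman_test(co$co_count, mu$co_count)
    data.frame(bin_size = size, n_bins = st$n, rho = st$rho, p = st$p,
               flagged = st$flagged)
  })
  do.call(rbind, rows)
}
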