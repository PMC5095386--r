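# independent brute-force oracles and small constructors shared by the suite

# all permutations of a vector (row-wise), for exhaustive rank tests
perm_all <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L))
  do.call(rbind, lapply(seq_len(n),
                        function(i) cbind(v[i], perm_all(v[-i]))))
}

# exhaustive-permutation Spearman (rho by rank arithmetic, two-sided p by
# full enumeration); feasible for n <= 6
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  perms <- perm_all(seq_along(x))
  rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# per-prefix recomputation of the block-extension walk: score of absorbing
# the first t gap markers, maximum then furthest tie
oracle_walk <- function(gap, block_label) {
  scores <- c(0, vapply(seq_along(gap), function(t)
    sum(gap[1:t] == block_label) - sum(gap[1:t] != block_label),
    numeric(1)))
  max(which(scores == max(scores))) - 1L
}

# all-pairs, all-sites diversity of a single window
oracle_diversity <- function(geno, min_site_frac = 0.5) {
  n <- ncol(geno); s <- nrow(geno)
  diffs <- numeric(0); n_inf <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(geno[, i]) & !is.na(geno[, j])
    if (sum(ok) / s > min_site_frac) {
      n_inf <- n_inf + 1L
      diffs <- c(diffs, sum(abs(geno[ok, i] - geno[ok, j]) / 2) / sum(ok))
    }
  }
  list(mean = if (n_inf) mean(diffs) else NA_real_, n = n_inf)
}

# build a marker_matrix directly from a genotype-code matrix
make_mm <- function(pos, geno, chrom = "chr1", f1 = "F1") {
  stopifnot(!is.null(colnames(geno)))
  structure(list(
    markers = data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
                         ref = "A", alt = "T", stringsAsFactors = FALSE),
    geno = geno, samples = colnames(geno), f1 = f1
  ), class = "marker_matrix")
}

# build a variant_records object from matrices
make_records <- function(pos, ad_ref, ad_alt, dp = ad_ref + ad_alt,
                         chrom = "chr1", qual = 99, biallelic = TRUE,
                         f1 = "F1") {
  structure(list(
    sites = data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
                       ref = "A", alt = "T",
                       qual = rep_len(qual, length(pos)),
                       biallelic = rep_len(biallelic, length(pos)),
                       stringsAsFactors = FALSE),
    dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
    samples = colnames(ad_ref), f1 = f1
  ), class = "variant_records")
}

# uniform event table on a genome, for calibration suites
uniform_events <- function(n, chrom_lengths) {
  cum <- cumsum(as.numeric(chrom_lengths))
  u <- stats::runif(n, 0, sum(chrom_lengths))
  ci <- findInterval(u, c(0, cum[-length(cum)]))
  data.frame(chrom = names(chrom_lengths)[ci], midpoint = u - c(0, cum)[ci],
             stringsAsFactors = FALSE)
}
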