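#' Configuration for the synthetic selfed-F2 cross simulator
#'
#' Bundles and validates every parameter of the simulator. The simulated
#' design mirrors a selfed-F2 sequencing experiment: a single heterozygous
#' F1, whose two phased haplotypes disagree at every marker, is selfed; each
#' F2 inherits two independent gametes of that F1; gametes recombine with a
#' Poisson number of crossovers per chromosome; each marker is then
#' "sequenced" by Poisson total depth and binomial allele-depth sampling.
#'
#' @param chrom_lengths named numeric vector, chromosome lengths in bp.
#' @param marker_density markers per kbp (markers heterozygous in the F1).
#'   May be a single value or named per chromosome.
#' @param n_f2 number of selfed F2 samples.
#' @param mean_co_per_gamete expected crossovers per gamete per chromosome;
#'   single value or named per chromosome.
#' @param intensity_map optional data frame `chrom,start,end,weight` of
#'   relative crossover weights; positions are placed by weighted window
#'   choice then uniformly within the window. `NULL` means uniform.
#' @param depth_mean mean sequencing depth (reads).
#' @param base_error per-read per-site miscall probability; homozygous
#'   markers yield alt-read fraction `base_error` (or `1 - base_error`).
#' @param geno_error probability a true genotype is replaced by a random
#'   other genotype before allele-depth sampling.
#' @param artifact_regions optional data frame `chrom,start,end` (0-based
#'   half-open) of pseudo-heterozygous regions: markers inside are forced to
#'   ~0.5 allele ratio in every sample, emulating collapsed paralogs.
#' @param mutation_rate expected de novo mutations per F2 genome.
#' @param co_coupling_fraction fraction of mutations placed within
#'   `coupling_window` bp of a true crossover of the same F2.
#' @param coupling_window bp radius used for coupled mutation placement.
#' @param seed integer RNG seed (< 2^31 - 16; nearby derived seeds are used
#'   for the independent simulation stages).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths,
                       marker_density = 1.5,
                       n_f2 = 24,
                       mean_co_per_gamete = 0.75,
                       intensity_map = NULL,
                       depth_mean = 50,
                       base_error = 0.01,
                       geno_error = 0.001,
                       artifact_regions = NULL,
                       mutation_rate = 0,
                       co_coupling_fraction = 0,
                       coupling_window = 2000,
                       seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("all chromosome lengths must be > 0")
  chroms <- names(chrom_lengths)
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      return(stats::setNames(rep(unname(x), length(chroms)), chroms))
    if (!all(chroms %in% names(x)))
      stop(what, " must be a single value or named for every chromosome")
    x[chroms]
  }
  marker_density <- expand(marker_density, "marker_density")
  mean_co_per_gamete <- expand(mean_co_per_gamete, "mean_co_per_gamete")
  if (any(marker_density <= 0)) stop("marker densities must be > 0")
  if (any(mean_co_per_gamete < 0)) stop("mean_co_per_gamete must be >= 0")
  for (p in c(base_error, geno_error, co_coupling_fraction))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (n_f2 < 1) stop("n_f2 must be >= 1")
  if (!is.null(intensity_map)) {
    stopifnot(all(c("chrom", "start", "end", "weight") %in%
                    colnames(intensity_map)))
    if (any(intensity_map$weight < 0))
      stop("intensity weights must be non-negative")
    w <- tapply(intensity_map$weight, intensity_map$chrom, sum)
    if (any(w <= 0))
      stop("intensity weights must sum > 0 per chromosome")
  }
  if (!is.null(artifact_regions))
    stopifnot(all(c("chrom", "start", "end") %in% colnames(artifact_regions)))
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0 || seed > 2^31 - 16)
    stop("seed must be an integer in [0, 2^31 - 16]")
  structure(list(
    chrom_lengths = chrom_lengths, marker_density = marker_density,
    n_f2 = as.integer(n_f2), mean_co_per_gamete = mean_co_per_gamete,
    intensity_map = intensity_map, depth_mean = depth_mean,
    base_error = base_error, geno_error = geno_error,
    artifact_regions = artifact_regions, mutation_rate = mutation_rate,
    co_coupling_fraction = co_coupling_fraction,
    coupling_window = coupling_window, seed = seed
  ), class = "sim_config")
}

#' Simulate F1-heterozygous marker positions
#'
#' Draws `round(density * length_kbp)` marker positions uniformly (without
#' replacement) on each chromosome. Every marker is heterozygous in the F1;
#' the F1 phase is recorded as the allele carried by haplotype 1 (0 =
#' reference, 1 = alternate), drawn by fair coin per marker.
#'
#' @param config a [sim_config()].
#' @return Data frame `chrom, pos, f1_hap1` sorted by chromosome (in
#'   `chrom_lengths` order) then position; `pos` is 1-based.
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  out <- lapply(names(config$chrom_lengths), function(cn) {
    len <- config$chrom_lengths[[cn]]
    n <- round(config$marker_density[[cn]] * len / 1000)
    if (n < 1)
      stop("marker density rounds to zero markers on chromosome ", cn)
    pos <- sort(sample.int(len, n))
    data.frame(chrom = cn, pos = pos,
               f1_hap1 = as.integer(stats::runif(n) < 0.5),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate one recombinant gamete of the F1 on one chromosome
#'
#' The crossover count is Poisson with the configured per-chromosome mean;
#' breakpoint positions are uniform over the chromosome unless an
#' `intensity_map` is configured, in which case windows are chosen with
#' probability proportional to their weight and positions drawn uniformly
#' within the chosen window. The starting haplotype is chosen by fair coin
#' and alternates at each breakpoint. Uses the current RNG state (callers
#' control the seed).
#'
#' @param config a [sim_config()].
#' @param chrom chromosome name.
#' @return List with `breakpoints` (sorted numeric bp) and `start_hap`
#'   (1 or 2).
#' @export
simulate_gamete <- function(config, chrom) {
  stopifnot(inherits(config, "sim_config"))
  len <- config$chrom_lengths[[chrom]]
  if (is.null(len) || is.na(len)) stop("unknown chromosome: ", chrom)
  n_co <- stats::rpois(1L, config$mean_co_per_gamete[[chrom]])
  if (n_co == 0L) {
    bp <- numeric(0)
  } else if (is.null(config$intensity_map)) {
    bp <- sort(stats::runif(n_co, 0, len))
  } else {
    im <- config$intensity_map[config$intensity_map$chrom == chrom, ,
                               drop = FALSE]
    if (nrow(im) == 0L) {
      bp <- sort(stats::runif(n_co, 0, len))
    } else {
      w <- sample.int(nrow(im), n_co, replace = TRUE, prob = im$weight)
      bp <- sort(stats::runif(n_co, im$start[w], im$end[w]))
    }
  }
  list(breakpoints = bp, start_hap = if (stats::runif(1) < 0.5) 1L else 2L)
}

# haplotype index (1/2) of a gamete at each marker position
gamete_haplotype_at <- function(pos, gamete) {
  k <- findInterval(pos, gamete$breakpoints)
  ifelse(k %% 2L == 0L, gamete$start_hap, 3L - gamete$start_hap)
}

#' Simulate a selfed-F2 population with sequencing noise
#'
#' Simulates markers, two independent gametes per F2 per chromosome, true
#' genotypes, and observed allele depths: total depth ~ Poisson(depth_mean),
#' alternate reads ~ Binomial(depth, p) with p in {base_error, 0.5,
#' 1 - base_error} according to the (possibly genotyping-error-corrupted)
#' genotype. Markers inside `artifact_regions` are forced to p = 0.5 in all
#' samples. The F1 itself is also "sequenced" (truly heterozygous at every
#' marker) as the first sample column.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_result` with elements `records` (a
#'   `variant_records` object, see [filter_variants()]) and `truth` (a
#'   `truth_set`: `breakpoints` data frame `sample,chrom,gamete,pos`,
#'   `phase_starts`, `markers`, and `genotypes`, the true 0/1/2 matrix).
#' @export
simulate_f2_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  markers <- simulate_markers(config)
  withr::local_seed(config$seed + 1L)
  chroms <- names(config$chrom_lengths)
  samples <- c("F1", sprintf("F2_%02d", seq_len(config$n_f2)))
  n_m <- nrow(markers)
  n_s <- length(samples)

  g_true <- matrix(NA_integer_, n_m, n_s, dimnames = list(NULL, samples))
  g_true[, "F1"] <- 1L
  n_gam <- length(chroms) * config$n_f2 * 2L
  bp_pos <- vector("list", n_gam)
  gam_sample <- character(n_gam)
  gam_chrom <- character(n_gam)
  gam_idx <- integer(n_gam)
  gam_start <- integer(n_gam)
  gi <- 0L

  for (cn in chroms) {
    idx <- which(markers$chrom == cn)
    pos <- markers$pos[idx]
    hap1_allele <- markers$f1_hap1[idx]
    for (s in seq_len(config$n_f2)) {
      sn <- samples[s + 1L]
      g1 <- simulate_gamete(config, cn)
      g2 <- simulate_gamete(config, cn)
      a1 <- ifelse(gamete_haplotype_at(pos, g1) == 1L,
                   hap1_allele, 1L - hap1_allele)
      a2 <- ifelse(gamete_haplotype_at(pos, g2) == 1L,
                   hap1_allele, 1L - hap1_allele)
      g_true[idx, sn] <- a1 + a2
      for (gm in 1:2) {
        g <- if (gm == 1L) g1 else g2
        gi <- gi + 1L
        bp_pos[[gi]] <- g$breakpoints
        gam_sample[gi] <- sn
        gam_chrom[gi] <- cn
        gam_idx[gi] <- gm
        gam_start[gi] <- g$start_hap
      }
    }
  }
  n_bp <- lengths(bp_pos)

  # artifact (pseudo-heterozygous) marker index
  artifact <- rep(FALSE, n_m)
  if (!is.null(config$artifact_regions)) {
    ar <- config$artifact_regions
    for (i in seq_len(nrow(ar))) {
      artifact <- artifact | (markers$chrom == ar$chrom[i] &
                                markers$pos > ar$start[i] &
                                markers$pos <= ar$end[i])
    }
  }

  dp <- matrix(0L, n_m, n_s, dimnames = list(NULL, samples))
  ad_alt <- matrix(0L, n_m, n_s, dimnames = list(NULL, samples))
  p_by_geno <- c(config$base_error, 0.5, 1 - config$base_error)
  for (s in seq_len(n_s)) {
    g <- g_true[, s]
    if (config$geno_error > 0) {
      flip <- stats::runif(n_m) < config$geno_error
      nf <- sum(flip)
      if (nf)
        g[flip] <- (g[flip] + sample(1:2, nf, replace = TRUE)) %% 3L
    }
    p <- p_by_geno[g + 1L]
    p[artifact] <- 0.5
    d <- stats::rpois(n_m, config$depth_mean)
    a <- stats::rbinom(n_m, d, p)
    dp[, s] <- d
    ad_alt[, s] <- a
  }
  ad_ref <- dp - ad_alt

  records <- structure(list(
    sites = data.frame(chrom = markers$chrom, pos = markers$pos,
                       ref = "A", alt = "T", qual = 99,
                       biallelic = TRUE, stringsAsFactors = FALSE),
    dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
    samples = samples, f1 = "F1"
  ), class = "variant_records")

  truth <- structure(list(
    breakpoints = data.frame(sample = rep(gam_sample, n_bp),
                             chrom = rep(gam_chrom, n_bp),
                             gamete = rep(gam_idx, n_bp),
                             pos = unlist(bp_pos),
                             stringsAsFactors = FALSE),
    phase_starts = data.frame(sample = gam_sample, chrom = gam_chrom,
                              gamete = gam_idx, start_hap = gam_start,
                              stringsAsFactors = FALSE),
    markers = markers,
    genotypes = g_true
  ), class = "truth_set")

  structure(list(records = records, truth = truth, config = config),
            class = "sim_result")
}

#' Inject de novo mutations, optionally coupled to crossovers
#'
#' Per F2, draws a Poisson(`mutation_rate`) number of mutations. A
#' `co_coupling_fraction` of them is placed uniformly within
#' +/- `coupling_window` bp of a uniformly chosen true crossover of the same
#' F2 (clipped to the chromosome); the remainder is uniform genome-wide
#' (chromosome chosen by length). If coupling is requested for an F2 with no
#' crossovers, that mutation falls back to uniform placement (with a
#' message). Positions colliding with marker positions are redrawn.
#'
#' @param config a [sim_config()].
#' @param truth the `truth_set` from [simulate_f2_population()].
#' @param seed RNG seed; defaults to `config$seed + 2`.
#' @return Data frame `sample, chrom, pos, near_co` (logical: placed by the
#'   coupling mechanism).
#' @export
inject_mutations <- function(config, truth, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_set"))
  withr::local_seed(seed)
  lens <- config$chrom_lengths
  chroms <- names(lens)
  marker_key <- paste(truth$markers$chrom, truth$markers$pos)
  samples <- sprintf("F2_%02d", seq_len(config$n_f2))
  bp <- truth$breakpoints
  out <- list()
  n_fallback <- 0L
  draw_coupled <- function(co_s, n) {
    j <- sample.int(nrow(co_s), n, replace = TRUE)
    cn <- co_s$chrom[j]
    p <- round(co_s$pos[j] + stats::runif(n, -config$coupling_window,
                                          config$coupling_window))
    list(chrom = cn, pos = pmax(1, pmin(lens[cn], p)))
  }
  draw_uniform <- function(n) {
    cn <- sample(chroms, n, replace = TRUE, prob = lens)
    list(chrom = cn, pos = floor(stats::runif(n, 0, lens[cn])) + 1)
  }
  for (sn in samples) {
    n_mut <- stats::rpois(1L, config$mutation_rate)
    if (n_mut == 0L) next
    co_s <- bp[bp$sample == sn, , drop = FALSE]
    coupled <- stats::runif(n_mut) < config$co_coupling_fraction
    if (any(coupled) && nrow(co_s) == 0L) {
      n_fallback <- n_fallback + sum(coupled)
      coupled[] <- FALSE
    }
    chrom <- character(n_mut)
    pos <- numeric(n_mut)
    if (any(coupled)) {
      d <- draw_coupled(co_s, sum(coupled))
      chrom[coupled] <- d$chrom
      pos[coupled] <- d$pos
    }
    if (any(!coupled)) {
      d <- draw_uniform(sum(!coupled))
      chrom[!coupled] <- d$chrom
      pos[!coupled] <- d$pos
    }
    # positions colliding with marker sites are redrawn by their own
    # placement mechanism
    repeat {
      bad <- paste(chrom, pos) %in% marker_key
      if (!any(bad)) break
      bad_c <- bad & coupled
      if (any(bad_c)) {
        d <- draw_coupled(co_s, sum(bad_c))
        chrom[bad_c] <- d$chrom
        pos[bad_c] <- d$pos
      }
      bad_u <- bad & !coupled
      if (any(bad_u)) {
        d <- draw_uniform(sum(bad_u))
        chrom[bad_u] <- d$chrom
        pos[bad_u] <- d$pos
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      sample = sn, chrom = chrom, pos = as.numeric(pos),
      near_co = coupled, stringsAsFactors = FALSE)
  }
  if (n_fallback > 0L)
    message(n_fallback,
            " coupled mutation(s) fell back to uniform placement ",
            "(F2 without crossovers)")
  if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(), chrom = character(), pos = numeric(),
               near_co = logical())
}
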