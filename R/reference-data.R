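#' Published per-chromosome crossover summary for the peach selfed-F2 crosses
#'
#' Per-chromosome mean crossover (CO) counts per F2 and CO rates
#' (cM/Mbp) reported for a domesticated *Prunus persica* intraspecific
#' selfed-F2 cross (24 F2s, 286 COs in total) and a
#' *P. persica* x *P. davidiana* interspecific selfed-F2 cross
#' (30 F2s, 284 COs), on the eight peach chromosomes. These published
#' summaries serve as reference inputs for rate arithmetic, for deriving
#' physical chromosome lengths, and for configuring simulations that emulate
#' the study design.
#'
#' @return A data frame with one row per chromosome (`Pp01`..`Pp08`) and
#'   columns `chrom`, `intra_mean_co`, `intra_rate`, `inter_mean_co`,
#'   `inter_rate`. Rates are in cM/Mbp; mean CO counts are per F2 (i.e. per
#'   two gametes).
#' @seealso [derive_chrom_lengths()], [peach_reference_stats()],
#'   [peach_sim_config()]
#' @export
#' @examples
#' tab <- peach_co_table()
#' co_rate(sum(tab$intra_mean_co), sum(derive_chrom_lengths(tab)))
peach_co_table <- function() {
  data.frame(
    chrom = sprintf("Pp%02d", 1:8),
    intra_mean_co = c(2.08, 1.63, 1.54, 1.33, 1.58, 1.08, 1.46, 1.21),
    intra_rate    = c(2.18, 2.67, 2.82, 2.58, 4.28, 1.76, 3.26, 2.68),
    inter_mean_co = c(1.60, 1.27, 1.23, 1.10, 1.17, 1.00, 1.07, 1.03),
    inter_rate    = c(1.67, 2.08, 2.25, 2.13, 3.15, 1.63, 2.38, 2.29),
    stringsAsFactors = FALSE
  )
}

#' Derive physical chromosome lengths from mean CO counts and CO rates
#'
#' Inverts the rate definition rate = mean_co * 50 / length_Mbp, so
#' length_Mbp = mean_co * 50 / rate. Applied to a published per-chromosome
#' summary this recovers the physical lengths (in Mbp) that the rates were
#' computed against.
#'
#' @param co_table data frame as returned by [peach_co_table()].
#' @param group which group's columns to invert: `"intra"` (default) or
#'   `"inter"`.
#' @return Named numeric vector of chromosome lengths in Mbp.
#' @export
derive_chrom_lengths <- function(co_table = peach_co_table(),
                                 group = c("intra", "inter")) {
  group <- match.arg(group)
  mean_co <- co_table[[paste0(group, "_mean_co")]]
  rate <- co_table[[paste0(group, "_rate")]]
  stats::setNames(mean_co * 50 / rate, co_table$chrom)
}

#' Published genome-wide summary statistics for the peach crosses
#'
#' Genome-wide reference values from the same study design as
#' [peach_co_table()]: total CO counts and sample sizes per group, F1
#' heterozygosity per group, and the hotspot/coldspot summary (region counts,
#' combined spans in Mbp, and mean CO rates in cM/Mbp).
#'
#' @return A list with elements `total_cos` (named: intra, inter), `n_f2`
#'   (named: intra, inter), `f1_heterozygosity_pct` (named: intra_young,
#'   intra_old, inter; percent per site between the two F1 haplotypes),
#'   `hotspot` and `coldspot` (each a list with `n`, `span_Mbp`,
#'   `rate_cM_per_Mbp`).
#' @export
peach_reference_stats <- function() {
  list(
    total_cos = c(intra = 286, inter = 284),
    n_f2 = c(intra = 24, inter = 30),
    f1_heterozygosity_pct = c(intra_young = 0.29, intra_old = 0.27,
                              inter = 1.24),
    hotspot = list(n = 26, span_Mbp = 19, rate_cM_per_Mbp = 8.04),
    coldspot = list(n = 14, span_Mbp = 53.8, rate_cM_per_Mbp = 0.48)
  )
}

#' Simulation configuration emulating the intraspecific peach cross
#'
#' Builds a [sim_config()] whose chromosome lengths are derived from the
#' published per-chromosome summary ([derive_chrom_lengths()]) and whose
#' per-gamete expected CO counts per chromosome equal the published per-F2
#' means divided by two (an F2 carries two independent gametes). Defaults
#' emulate the intraspecific study group: 24 F2s, ~1.5 markers/kbp, mean
#' depth 50x.
#'
#' @param n_f2 number of selfed F2 samples.
#' @param marker_density markers per kbp.
#' @param depth_mean mean sequencing depth.
#' @param base_error per-read per-site error probability.
#' @param geno_error probability that a true genotype is replaced by a
#'   random other genotype before depth sampling.
#' @param seed integer RNG seed.
#' @param ... further arguments passed to [sim_config()].
#' @return A `sim_config` object.
#' @export
peach_sim_config <- function(n_f2 = 24, marker_density = 1.5,
                             depth_mean = 50, base_error = 0.01,
                             geno_error = 0.001, seed = 1L, ...) {
  len_mbp <- derive_chrom_lengths()
  tab <- peach_co_table()
  sim_config(
    chrom_lengths = round(len_mbp * 1e6),
    marker_density = marker_density,
    n_f2 = n_f2,
    mean_co_per_gamete = stats::setNames(tab$intra_mean_co / 2, tab$chrom),
    depth_mean = depth_mean,
    base_error = base_error,
    geno_error = geno_error,
    seed = seed,
    ...
  )
}
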