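#' Select the reference-haplotype sample for a chromosome
#'
#' In an intraspecific cross no parental genomes are available, so the two
#' F1 haplotypes are unknown. However, an F2 whose chromosome shows only
#' homozygous confident calls carries two copies of a single F1 haplotype;
#' its alleles define "haplotype 1" and every other sample can be phased
#' against it. Among such all-homozygous F2s the one with the most
#' informative markers is chosen.
#'
#' @param matrix_obj a `marker_matrix`.
#' @param chrom chromosome name.
#' @return The selected sample name.
#' @export
select_reference_haplotype <- function(matrix_obj, chrom) {
  stopifnot(inherits(matrix_obj, "marker_matrix"))
  idx <- which(matrix_obj$markers$chrom == chrom)
  if (!length(idx)) stop("no markers on chromosome ", chrom)
  f2 <- setdiff(matrix_obj$samples, matrix_obj$f1)
  g <- matrix_obj$geno[idx, f2, drop = FALSE]
  n_inf <- colSums(!is.na(g))
  all_hom <- colSums(g == 1L, na.rm = TRUE) == 0L & n_inf > 0L
  if (!any(all_hom))
    stop("no all-homozygous F2 found on chromosome ", chrom,
         "; phasing needs a sample with two identical haplotypes. ",
         "Consider relaxing with a longest-homozygous-tract fallback ",
         "or inspecting the chromosome manually.")
  f2[all_hom][which.max(n_inf[all_hom])]
}

#' Phase an intraspecific chromosome against a reference haplotype
#'
#' Relabels every confident homozygous call as `hap1` if it matches the
#' reference sample's (homozygous) allele at that marker, `hap2` otherwise;
#' heterozygous calls keep label `het`. Markers where the reference sample
#' is missing cannot assign a haplotype to homozygous calls; those calls
#' are excluded (set `NA`) and counted in the `n_unphased` attribute.
#' Crossover midpoints are invariant to which F1 haplotype the reference
#' happens to carry (swapping it only swaps `hap1`/`hap2` labels).
#'
#' @param matrix_obj a `marker_matrix`.
#' @param chrom chromosome name.
#' @param ref_sample reference sample, e.g. from
#'   [select_reference_haplotype()].
#' @return Character matrix (chromosome markers x samples) with labels
#'   `hap1`, `hap2`, `het`, `NA`; attributes `marker_idx` (row indices into
#'   the matrix markers), `ref_sample` and `n_unphased`.
#' @export
phase_intraspecific <- function(matrix_obj, chrom, ref_sample) {
  stopifnot(inherits(matrix_obj, "marker_matrix"),
            ref_sample %in% matrix_obj$samples)
  idx <- which(matrix_obj$markers$chrom == chrom)
  g <- matrix_obj$geno[idx, , drop = FALSE]
  ref <- g[, ref_sample]
  if (any(ref == 1L, na.rm = TRUE))
    stop("reference sample ", ref_sample, " has heterozygous calls on ",
         chrom, "; not a valid haplotype reference")
  lab <- matrix(NA_character_, nrow(g), ncol(g),
                dimnames = dimnames(g))
  lab[g == 1L] <- "het"
  hom <- !is.na(g) & g != 1L
  ref_ok <- !is.na(ref)           # recycles down columns
  match_ref <- hom & ref_ok & g == ref
  lab[match_ref] <- "hap1"
  lab[hom & ref_ok & !match_ref] <- "hap2"
  structure(lab, marker_idx = idx, ref_sample = ref_sample,
            n_unphased = sum(hom & !ref_ok))
}

#' Phase every chromosome of an intraspecific marker matrix
#'
#' Applies [select_reference_haplotype()] and [phase_intraspecific()] per
#' chromosome and assembles a full-size phased label matrix suitable for
#' [call_crossovers_all()].
#'
#' @param matrix_obj a `marker_matrix`.
#' @return Character matrix (all markers x samples); attribute
#'   `ref_samples` names the reference chosen per chromosome.
#' @export
phase_population <- function(matrix_obj) {
  stopifnot(inherits(matrix_obj, "marker_matrix"))
  out <- matrix(NA_character_, nrow(matrix_obj$geno),
                ncol(matrix_obj$geno),
                dimnames = dimnames(matrix_obj$geno))
  refs <- character(0)
  for (cn in unique(matrix_obj$markers$chrom)) {
    rs <- select_reference_haplotype(matrix_obj, cn)
    ph <- phase_intraspecific(matrix_obj, cn, rs)
    out[attr(ph, "marker_idx"), ] <- ph
    refs[cn] <- rs
  }
  structure(out, ref_samples = refs)
}

#' Genotype interspecific F2s against the two parental genomes
#'
#' At markers where the two parents carry reciprocal homozygous genotypes,
#' an F2 homozygous call is labelled `A_hom` or `B_hom` according to which
#' parent's allele it matches; heterozygous calls are labelled `het`.
#' Markers where the parents are not reciprocally informative (either
#' heterozygous, missing, or sharing the allele) are dropped (`NA` row),
#' with the count reported via attribute `n_dropped`.
#'
#' @param matrix_obj a `marker_matrix` whose samples include both parents.
#' @param parent_a,parent_b parental sample names (A = domesticated-parent
#'   convention).
#' @return Character matrix (all markers x samples) with labels `A_hom`,
#'   `B_hom`, `het`, `NA`; attribute `n_dropped`.
#' @export
genotype_interspecific <- function(matrix_obj, parent_a, parent_b) {
  stopifnot(inherits(matrix_obj, "marker_matrix"),
            all(c(parent_a, parent_b) %in% matrix_obj$samples))
  g <- matrix_obj$geno
  pa <- g[, parent_a]
  pb <- g[, parent_b]
  informative <- !is.na(pa) & !is.na(pb) & pa != 1L & pb != 1L & pa != pb
  lab <- matrix(NA_character_, nrow(g), ncol(g), dimnames = dimnames(g))
  inf_m <- matrix(informative, nrow(g), ncol(g))
  lab[inf_m & g == 1L] <- "het"
  hom <- inf_m & !is.na(g) & g != 1L
  match_a <- hom & g == matrix(pa, nrow(g), ncol(g))
  lab[match_a] <- "A_hom"
  lab[hom & !match_a] <- "B_hom"
  structure(lab, n_dropped = sum(!informative))
}

#' Compare called crossovers with simulated truth
#'
#' Greedy one-to-one matching per sample and chromosome: each true gamete
#' breakpoint is matched to the first unused called event whose interval
#' `[left, right]` contains it. Reports recall, precision, the mean
#' absolute midpoint error of matched events, and the mean local
#' half-resolution (half the matched event's marker interval) as the
#' natural error bound.
#'
#' @param events events data frame from [call_crossovers_all()].
#' @param truth a `truth_set` from [simulate_f2_population()].
#' @return List `n_true, n_called, n_matched, recall, precision,
#'   mean_abs_midpoint_error, mean_half_resolution`.
#' @export
evaluate_co_calls <- function(events, truth) {
  stopifnot(inherits(truth, "truth_set"))
  tb <- truth$breakpoints
  key_t <- paste(tb$sample, tb$chrom)
  key_e <- paste(events$sample, events$chrom)
  n_matched <- 0L
  err <- numeric(0)
  halfres <- numeric(0)
  for (k in unique(key_t)) {
    bp <- sort(tb$pos[key_t == k])
    ev <- events[key_e == k, , drop = FALSE]
    ev <- ev[order(ev$left), , drop = FALSE]
    used <- rep(FALSE, nrow(ev))
    for (b in bp) {
      cand <- which(!used & ev$left <= b & ev$right >= b)
      if (length(cand)) {
        j <- cand[1L]
        used[j] <- TRUE
        n_matched <- n_matched + 1L
        err <- c(err, abs(ev$midpoint[j] - b))
        halfres <- c(halfres, ev$resolution[j] / 2)
      }
    }
  }
  list(n_true = nrow(tb), n_called = nrow(events), n_matched = n_matched,
       recall = n_matched / nrow(tb),
       precision = n_matched / nrow(events),
       mean_abs_midpoint_error = mean(err),
       mean_half_resolution = mean(halfres))
}
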