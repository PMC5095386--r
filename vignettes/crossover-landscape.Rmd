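---
title: "Crossover landscapes from selfed F2 sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover landscapes from selfed F2 sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coscape)
```

## The problem

A heterozygous F1 tree is self-fertilised and its F2 progeny are sequenced
at high depth together with the F1. Every site at which the F1 is
confidently heterozygous is a *marker*: the genotype an F2 shows at that
site reveals which combination of the two F1 haplotypes it inherited.
Along a chromosome, an F2's genotype sequence is piecewise constant —
maximal runs of one genotype are *inherited blocks* — and each switch
between adjacent blocks localises a meiotic crossover (CO) to the interval
between the two flanking markers. Pooled over a population of F2s, the CO
midpoints define a recombination landscape that can be scanned for
hotspots and coldspots, converted to genetic map units, and correlated
with de novo mutations and population diversity.

`coscape` implements this chain end to end for selfed-F2 designs, plus a
synthetic-cross simulator that provides exact ground truth (every gamete's
breakpoints, every haplotype, every planted mutation) so that each stage
can be validated without any external sequencing data.

## Marker filtering

Raw multi-sample variant records pass four gates
(`classify_genotype()`, `filter_variants()`):

* bi-allelic records with quality >= 50;
* per-sample depth within [10, 80] (outside, the call is `MISSING`);
* allele balance: reference-allele ratio >= 0.95 (`HOM_REF`),
  <= 0.05 (`HOM_ALT`), or in [0.30, 0.70] (`HET`); anything between the
  bands is `MISSING`;
* census: strictly more than half of the samples informative, and the F1
  confidently `HET`.

Three readings the record format leaves open are fixed as follows. The
depth bounds apply per sample to the DP field (a `depth_source = "ad_sum"`
mode exists); the allele ratio always uses the AD sum, since AD counts the
genotyped reads while DP includes uninformative ones. Ambiguous-balance
calls become `MISSING` rather than dropping the whole record, which
preserves the census semantics. "More than half" is a strict inequality:
an exact tie drops the site. Indel and SNP markers are treated
identically once bi-allelic.

Pseudo-heterozygosity — reads from collapsed paralogs or structural
variants piling onto one locus — produces artefactual `HET` calls that
masquerade as inherited blocks. `build_sv_mask()` turns a union of SV
calls (deletions, duplications, inversions, translocations from multiple
callers, unfiltered) into mask intervals: SVs under 100 kbp are masked
whole, inversions with 200 bp flanks; SVs of 100 kbp or more contribute
only 400 bp flanks around each breakpoint, because masking a megabase-
scale CNV entirely would discard well-behaved interior markers. A second,
advisory diagnostic (`flag_marker_clusters()`) flags sliding 25-marker
runs whose adjacent-gap standard error exceeds 100 bp — artefactual
marker pile-ups have wildly uneven spacing. The 25-marker run mirrors the
seed size; the windowing is our choice, as the diagnostic is defined only
by its threshold.

## Seed-and-extend block segmentation

Blocks are built per sample and chromosome from the informative markers
(`MISSING` calls are transparent: they never break a run, a strict mode is
available via the seeding parameters):

1. **Seeds** (`find_seeds()`): maximal runs of at least `k = 25`
   same-genotype markers spanning strictly more than 10 kbp.
2. **Merge** (`merge_seeds()`): consecutive seeds of one genotype with no
   opposing seed between them fuse, absorbing the unseeded markers
   between (absorbed disagreements are counted per block, never hidden).
3. **Extend** (`extend_blocks()`): each block edge walks outward across
   unassigned markers, scoring +1 for a matching and -1 for a
   non-matching marker; the new boundary is the furthest matching marker
   at which the cumulative score attains its maximum. This is our
   operationalisation of extending "until the proportion of the genotype
   starts to decline": the cumulative-score maximum is exactly the point
   beyond which matches are outnumbered, it is order-independent, and on
   ties the furthest marker wins. When the two blocks flanking a gap both
   reach into it, the split maximising the sum of the two scores is used
   (ties split at the middle marker).

`call_crossovers()` emits one event per adjacent block pair, located
between the last marker of the upstream and the first marker of the
downstream block, summarised by the floor midpoint. An adjacency of two
*opposite homozygous* blocks would require two crossovers between two
adjacent markers — astronomically unlikely for independent gametes — so
it is emitted as two coincident events with a warning rather than being
silently dropped.

Boundary review is deliberately non-interactive: instead of manual
inspection, the block tables carry per-block mismatch counts and
per-event resolutions, which a user can rank and inspect.

## Phasing without parents

In an intraspecific cross the two F1 haplotypes are unknown, so markers
can initially only be genotyped `hom`/`het`. Because the two chromosomes
of an F2 come from independent meioses, a genotype switch still means one
crossover, and CO *counting* needs no phasing. To recover haplotype
identity (`hap1`/`hap2`), `select_reference_haplotype()` finds, per
chromosome, an F2 whose confident calls are all homozygous: such a sample
carries two copies of a single F1 haplotype, which defines "haplotype 1";
every other sample's homozygous calls are then relabelled by comparison
(`phase_intraspecific()`). CO midpoints are invariant to which haplotype
the reference happens to carry — swapping it swaps labels only.

Two design points. First, when the reference sample is missing at a
marker, that marker's homozygous calls in other samples are excluded from
the phased sequence (and counted) rather than being kept under a mixed
"unphased hom" label: a third label in the phased space would corrupt the
alternation invariant of merging. Second, when no all-homozygous sample
exists — the probability one exists falls roughly as
$(1/2)e^{-2\lambda}$ per F2 with the per-gamete map length $\lambda$ —
the function stops with guidance instead of silently inventing a
reference; a longest-homozygous-tract fallback is a possible extension
but is not default behaviour. The interspecific path
(`genotype_interspecific()`) sidesteps all of this by labelling F2
homozygotes directly against the two parents at reciprocally informative
markers.

## Landscape statistics

Map-unit conversion (`co_rate()`): an F2 genotype records the outcomes of
two independent gametes, so the genetic length in cM is
$(\overline{CO}/2) \times 100$ and the rate is
$\overline{CO} \cdot 50 / L_{Mbp}$.

Hotspots and coldspots (`window_counts()`, `merge_similar()`,
`randomization_test()`): CO midpoints are counted in non-overlapping
500-kbp windows (half-open; a boundary midpoint belongs to the right
window); adjacent windows with similar counts are merged (default
tolerance 0, i.e. identical counts — the minimal reading of "similar",
configurable); each merged region is then tested against 10 000
randomizations that re-place all events uniformly over the genome
(optionally over the complement of a mask). We use the add-one estimator
$p = (1 + \#\{rand \ge obs\})/(1 + n_{rand})$ so that no finite shuffle
reports $p = 0$, and apply the significance level per region without
multiplicity correction, which matches how such scans are conventionally
reported. Region rates and the hotspot/coldspot contrast use a Welch
two-sample t-test across region rates ("t-test" is underspecified;
unequal variances between hot and cold regions are the norm).

**A calibration caveat the test suite quantifies.** Merging windows *by
their observed counts* and then testing each merged region at its own
summed count is a selection effect: under a uniform null with 286 events
on a 225-Mbp genome, the suite measures a hotspot-flagged region fraction
of about 0.059 at $\alpha = 0.05$ (and a conservative 0.03 for
coldspots) over 200 replicate genomes. The procedure is therefore
slightly anti-conservative for hotspots as specified; users who need
exact region-level calibration should merge on fixed grids instead. We
report this honestly rather than altering the published procedure.

Rank correlations use `spearman_test()` — average-rank $\rho$ with the
exact permutation distribution for $n \le 9$ without ties (the
per-chromosome comparisons have $n = 8$) and the t-approximation
otherwise. Group-level rate comparisons use `brunner_munzel_test()`, a
nonparametric test of $P(X<Y) + \tfrac12 P(X=Y) = \tfrac12$ robust to
unequal variances; it is implemented here directly (with the Brunner &
Munzel 2000 t-approximation) and is cross-checked against a permutation
oracle in the tests.

## Mutation coupling

`nearest_co_distance()` measures each de novo mutation's distance to the
nearest CO midpoint — by default within the same sample, since mutagenic
recombination is an intra-genome mechanism; a pooled mode exists and is
always reported alongside. Distances use midpoints rather than interval
edges for consistency with the windowed statistics; an edge mode is
available because CO resolution (~kbp) is commensurate with the 2-kbp
radius of interest. `proximity_enrichment_test()` turns the descriptive
comparison into a one-sided permutation test (mutations re-placed
uniformly per chromosome). Because the statistic is a small discrete
count (at study scale the null expects ~0.1 mutations within 2 kbp of a
same-sample CO), its permutation p-value cannot be uniform under the
null: it is *super-uniform*, with most mass at $p = 1$. The meaningful
null property — the rejection rate never exceeds the nominal level — is
what the acceptance suite asserts, together with the power property that
simulated coupling of the size reported in other taxa (half of mutations
within 2 kbp) is detected in well over 90% of replicates.
`binned_correlation()` complements this with Spearman correlations of CO
and mutation counts in 0.5/1/2/5-Mbp bins, excluding peri-centromeric
bins where recombination suppression would induce a spurious positive
association.

## Windowed pairwise diversity

The population statistic (`window_diversity()`) is the average, over all
individual pairs, of per-site genotype differences: 1 between opposite
homozygotes, 0.5 between homozygote and heterozygote, and — a case the
scoring rule leaves implicit — 0 for two heterozygotes at a bi-allelic
site, since the unordered genotypes are identical. Per pair and window,
differences are summed and divided by the number of sites genotyped in
both individuals; a pair counts only if strictly more than 50% of the
window's sites are informative for it, and a window is retained only if
informative pairs reach `ceiling(0.5 * n(n-1)/2)` — 1208 of 2415 for 70
individuals, reproduced verbatim by the boundary tests. Site filters
(`site_filter()`) drop sites with more than half missing *alleles*
(allele-count reading; an individual-count mode is a documented
alternative) or non-reference allele count below 7.

## The simulator and what it does (not) emulate

`sim_config()` fixes the study conditions; the defaults emulate the
intraspecific design via `peach_sim_config()`: eight chromosomes whose
lengths (summing to 225.4 Mbp) are recovered by inverting the published
per-chromosome rates, 24 F2s, ~1.5 markers/kbp, mean depth 50x, and
per-gamete CO means set to half the published per-F2 means (5.96 per
gamete genome-wide). Model choices:

* **Poisson crossovers, no interference, no obligate chiasma.** The
  per-chromosome CO distribution family is an assumption of the
  simulator, not an inference about peach; interference would make
  breakpoints *more* regular, so the Poisson null is conservative for
  recovery testing. The per-window `intensity_map` provides
  non-uniformity when needed.
* **Uniform marker positions** — the simplest null consistent with the
  observed densities; clustering exists only to exercise the gap-SE
  diagnostic.
* **Poisson total depth, binomial allele depth** with
  $p \in \{e, 0.5, 1-e\}$ by genotype — the standard shotgun
  approximation given only a mean depth; a genotyping-error probability
  replaces the true genotype with a random other one before depth
  sampling.
* **Pseudo-heterozygous artifact regions** force a ~0.5 allele ratio in
  every sample, emulating collapsed paralogs (the phenomenon SV masking
  exists to remove).
* **Mutations** are Poisson per F2, with a configurable fraction placed
  within a window of a uniformly chosen *same-sample* crossover —
  mutagenic recombination acts within a genome — and the rest uniform.

Not emulated: read-level errors (FASTQ), indel realism, genuine SV
breakpoint geometry, interspecific divergence along the chromosome.
Passing recovery tests therefore demonstrates correctness of the calling
machinery under calibrated noise, not robustness to alignment artefacts
beyond the forced-heterozygosity model.

## Problem sizes and numerical choices in the suites

The validation suites run at the following sizes, chosen to make each
statistical check well-powered while keeping a full run to a few
minutes: study-scale recovery uses the full 225.4-Mbp, 24-F2,
~338 000-marker configuration (recall and precision are both >= 0.95
against truth, with mean midpoint error below the mean half-resolution);
randomization calibration uses 200 replicate genomes at 1000 shuffles;
coupling power and validity use 50 and 200 truth-level replicates at 199
permutations; the Mendelian check draws 25 000 genotypes at one marker
per chromosome across 2500 F2s, because chi-square requires independent
draws and markers within a chromosome are linked. Determinism is
end-to-end: every stochastic stage takes an explicit seed, and identical
configurations yield byte-identical outputs.

## Known limitations

* The hotspot scan's region-level p-values inherit a mild
  anti-conservativeness from count-based merging (quantified above).
* Intraspecific phasing requires an all-homozygous sample per
  chromosome; long chromosomes in large maps may lack one, in which case
  the package stops with guidance (CO counting is unaffected).
* Double crossovers between adjacent markers are invisible by
  construction; opposite-homozygote adjacencies are surfaced as warnings
  rather than resolved.
* The diversity statistic is a genotype-level $\pi$-like quantity; it is
  not an estimator of $\theta_W$ and no SFS machinery is provided.
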