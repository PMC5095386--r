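# coscape

Crossover-landscape analysis for selfed-F2 sequencing designs.

When a heterozygous F1 tree is self-fertilised and sequenced together
with its F2 progeny, every site at which the F1 is confidently
heterozygous becomes a marker: an F2's genotype there reveals which F1
haplotypes it inherited. Along each F2 chromosome the genotype sequence
is piecewise constant, and every switch between adjacent genotype blocks
localises one meiotic crossover (CO). `coscape` turns multi-sample
variant calls into that landscape:

* **Marker filtering** — allele-balance genotype classification
  (HOM at reference-allele ratio >= 95% or <= 5%, HET at 30-70%, depth
  10-80), quality/census filters, structural-variant masking and a
  marker-clustering diagnostic.
* **Block segmentation** — seed (25 consecutive same-genotype markers
  spanning > 10 kbp), merge, and score-based extension; CO events are
  called at block switches and summarised by midpoints. Intraspecific
  crosses are phased without parental genomes via an all-homozygous
  reference F2; interspecific crosses are genotyped against the parents.
* **Landscape statistics** — genetic-map conversion
  (rate = meanCO x 50 / Mbp, since an F2 carries two gametes), 500-kbp
  window counts, hotspot/coldspot detection by Monte-Carlo event
  shuffling, Spearman rank correlations (exact for n <= 9), and a
  Brunner-Munzel group comparison.
* **CO-mutation coupling** — distance-to-nearest-crossover tables, a
  permutation enrichment test, and binned rate correlations.
* **Windowed population diversity** — the 0 / 0.5 / 1 pairwise genotype
  difference averaged over all pairs, with informative-site and
  informative-pair retention rules.
* **A synthetic selfed-cross simulator** — Poisson crossovers per
  gamete, binomial allele-depth noise, genotyping error,
  pseudo-heterozygous artifact regions and (optionally CO-coupled) de
  novo mutations — providing exact ground truth for every stage.

## Worked example

A small bundled simulated cross (two chromosomes, ten F2s, ~30 000
markers at 50x depth with realistic noise):

```r
library(coscape)

fx <- make_fixture(seed = 20)
mm <- filter_variants(fx$sim$records)
calls <- call_crossovers_all(mm)

nrow(mm$markers)        # 29800 of 30000 simulated markers retained
nrow(calls$events)      # 39 crossovers called (39 in truth)
head(calls$events[, c("sample", "chrom", "left", "right", "midpoint")], 3)
#>   sample chrom    left   right midpoint
#> 1  F2_01  chr1 3028701 3030657  3029679
#> 2  F2_02  chr1 1221419 1222160  1221789
#> 3  F2_02  chr1 2065348 2067182  2066265

evaluate_co_calls(calls$events, fx$sim$truth)
#> recall 1.000  precision 1.000  mean midpoint error 274 bp

chrom_stats(calls$events, 10, fx$config$chrom_lengths)
#>   chrom mean_co length_Mbp rate_cM_per_Mbp
#> 1  chr1     2.0         12            8.33
#> 2  chr2     1.9          8           11.88
#> 3   All     3.9         20            9.75
```

Each called event is an interval between the last marker of one genotype
block and the first marker of the next; `midpoint` is its point summary
and `rate_cM_per_Mbp` converts mean CO counts per F2 into genetic map
units. Hotspot/coldspot scanning on the same events:

```r
w <- window_counts(calls$events, fx$config$chrom_lengths)   # 500-kbp windows
r <- randomization_test(merge_similar(w), fx$config$chrom_lengths,
                        nrow(calls$events), n_rand = 1000, seed = 1)
table(r$class)
#> coldspot  neutral
#>        3       26
```

`run_pipeline()` chains all stages (simulate or read VCF, filter, call,
landscape, coupling) into a JSON report with seeds and provenance;
`peach_sim_config()` configures the simulator to a published
peach-cross design (eight chromosomes, 225.4 Mbp, 24 F2s, ~1.5
markers/kbp, ~5.96 COs per gamete).

## Documentation

The methods vignette (`vignettes/crossover-landscape.Rmd`) documents the
model assumptions, every tunable threshold with its default and
rationale, what the simulator does and does not emulate, and known
limitations, including a measured calibration caveat of count-merged
hotspot regions.
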