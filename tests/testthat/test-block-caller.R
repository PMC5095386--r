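test_that("seeding requires 25 consecutive markers spanning over 10 kbp", {
  pos12 <- seq(0, 12000, length.out = 25)
  s <- find_seeds(pos12, rep("het", 25))
  expect_equal(nrow(s), 1)
  expect_equal(s$label, "het")

  pos9 <- seq(0, 9000, length.out = 25)
  expect_equal(nrow(find_seeds(pos9, rep("het", 25))), 0)
  # boundary: span exactly 10 kbp is not "over 10 kbp"
  expect_equal(nrow(find_seeds(seq(0, 10000, length.out = 25),
                               rep("het", 25))), 0)

  alt <- rep(c("het", "hom"), 30)
  expect_equal(nrow(find_seeds(seq(0, 6e4, length.out = 60), alt)), 0)
  expect_equal(nrow(find_seeds(numeric(0), character(0))), 0)
})

test_that("same-genotype seeds merge across unseeded noise into alternating blocks", {
  lab <- c(rep("het", 30), rep("hom", 5), rep("het", 30))
  pos <- seq(0, by = 1000, length.out = length(lab))
  seeds <- find_seeds(pos, lab)
  expect_equal(nrow(seeds), 2)           # the 5 "hom" cannot seed
  bl <- merge_seeds(seeds, lab)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$n_mismatch, 5L)
  expect_equal(bl$n_markers, 65L)

  lab2 <- c(rep("het", 30), rep("hom", 30), rep("het", 30))
  pos2 <- seq(0, by = 1000, length.out = 90)
  bl2 <- merge_seeds(find_seeds(pos2, lab2), lab2)
  expect_equal(bl2$label, c("het", "hom", "het"))
  expect_true(all(bl2$label[-1] != bl2$label[-3]))

  single <- merge_seeds(find_seeds(pos12 <- seq(0, 24000, length.out = 25),
                                   rep("hom", 25)), rep("hom", 25))
  expect_equal(nrow(single), 1)
})

test_that("block extension follows the cumulative-score rule (brute-force checked)", {
  # quoted example: trailing gap [H H H A H H] behind an H block extends
  # through all six markers (final score 4 is the maximum)
  lab <- c(rep("het", 25), "het", "het", "het", "hom", "het", "het")
  pos <- seq(0, by = 1000, length.out = length(lab))
  bl <- genotype_blocks(pos, lab)
  expect_equal(bl$end, 31L)
  expect_equal(bl$n_mismatch, 1L)

  # gap with zero matching markers: no extension
  lab0 <- c(rep("het", 25), "hom", "hom", "hom")
  bl0 <- genotype_blocks(seq(0, by = 1000, length.out = 28), lab0)
  expect_equal(bl0$end, 25L)

  # gap all matching: extends to the furthest marker
  lab1 <- c(rep("het", 25), rep("het", 7))
  bl1 <- genotype_blocks(seq(0, by = 1000, length.out = 32), lab1)
  expect_equal(bl1$end, 32L)

  # random gaps against the per-prefix oracle
  withr::with_seed(12, {
    for (i in 1:50) {
      gap <- sample(c("het", "hom"), sample(1:12, 1), replace = TRUE)
      lab <- c(rep("het", 25), gap)
      pos <- seq(0, by = 1000, length.out = length(lab))
      bl <- genotype_blocks(pos, lab)
      expect_equal(bl$end, 25L + oracle_walk(gap, "het"),
                   info = paste(gap, collapse = ","))
    }
  })
})

test_that("overlapping extensions split the gap at the joint-score maximum", {
  withr::with_seed(77, {
    for (i in 1:40) {
      gap <- sample(c("het", "hom"), sample(2:10, 1), replace = TRUE)
      lab <- c(rep("het", 25), gap, rep("hom", 25))
      pos <- seq(0, by = 1000, length.out = length(lab))
      bl <- genotype_blocks(pos, lab)
      expect_equal(nrow(bl), 2)
      expect_true(bl$end[1] < bl$start[2])
      # every gap marker is absorbed by exactly one side or neither,
      # and blocks stay alternating
      expect_true(bl$label[1] != bl$label[2])
      m <- length(gap)
      tL <- bl$end[1] - 25L
      tR <- 25L + m + 1L - bl$start[2]
      expect_lte(tL + tR, m)
      # when the independent walks overlap, verify the split maximizes
      # the summed scores (direct enumeration)
      if (oracle_walk(gap, "het") + oracle_walk(rev(gap), "hom") > m) {
        score <- function(cc) {
          sL <- if (cc > 0) sum(gap[1:cc] == "het") - sum(gap[1:cc] != "het") else 0
          rest <- if (cc < m) gap[(cc + 1):m] else character(0)
          sR <- sum(rest == "hom") - sum(rest != "hom")
          sL + sR
        }
        totals <- vapply(0:m, score, numeric(1))
        expect_equal(totals[tL + 1], max(totals))
      }
    }
  })
})

test_that("crossovers are called at block switches with midpoint localization", {
  expect_equal(nrow(call_crossovers(
    genotype_blocks(seq(0, 24000, 1000), rep("het", 25)))), 0)

  lab <- c(rep("hom", 25), rep("het", 25))
  pos <- c(seq(976000, by = 1000, length.out = 25),
           seq(1030000, by = 1000, length.out = 25))
  ev <- call_crossovers(genotype_blocks(pos, lab))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$left, 1000000)
  expect_equal(ev$right, 1030000)
  expect_equal(ev$midpoint, 1015000)
  expect_equal(ev$resolution, 30000)

  # opposite homozygotes imply two coincident crossovers
  lab2 <- c(rep("hap1", 25), rep("hap2", 25))
  pos2 <- seq(0, by = 1000, length.out = 50)
  expect_warning(ev2 <- call_crossovers(genotype_blocks(pos2, lab2)),
                 "two coincident")
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$midpoint[1], ev2$midpoint[2])
})

test_that("missing calls are transparent to seeding and calling", {
  lab <- c(rep("hom", 13), rep(NA, 20), rep("hom", 12), rep("het", 25))
  pos <- seq(0, by = 1000, length.out = length(lab))
  ev <- call_crossovers(genotype_blocks(pos, lab))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$from, "hom")
})

test_that("noiseless simulation is recovered with perfect precision", {
  cfg <- sim_config(chrom_lengths = c(c1 = 5e6, c2 = 3e6),
                    marker_density = 2, n_f2 = 8, mean_co_per_gamete = 1,
                    depth_mean = 10000, base_error = 0, geno_error = 0,
                    seed = 41)
  sim <- simulate_f2_population(cfg)
  mm <- filter_variants(sim$records, min_depth = 1, max_depth = 1e9)
  calls <- call_crossovers_all(mm)
  ev <- evaluate_co_calls(calls$events, sim$truth)
  expect_equal(ev$precision, 1)
  # every called midpoint lies between the true breakpoint's flanking
  # markers (interval containment is how matching is defined)
  expect_equal(ev$n_matched, ev$n_called)
  # determinism of the whole chain
  calls2 <- call_crossovers_all(filter_variants(
    simulate_f2_population(cfg)$records, min_depth = 1, max_depth = 1e9))
  expect_identical(calls, calls2)
  # block alternation per sample and chromosome
  bl <- calls$blocks
  for (k in unique(paste(bl$sample, bl$chrom))) {
    lb <- bl$label[paste(bl$sample, bl$chrom) == k]
    if (length(lb) > 1) expect_true(all(lb[-1] != lb[-length(lb)]))
  }
})

test_that("reference-haplotype selection picks the most informative all-homozygote", {
  g <- cbind(F1 = rep(1L, 60),
             a = rep(0L, 60),                        # all-hom, complete
             b = c(rep(0L, 50), rep(NA, 10)),        # all-hom, less informative
             c = rep(c(0L, 1L), 30))                 # has het calls
  mm <- make_mm(seq(0, by = 1000, length.out = 60), g)
  expect_equal(select_reference_haplotype(mm, "chr1"), "a")

  g2 <- g[, c("F1", "c")]
  mm2 <- make_mm(seq(0, by = 1000, length.out = 60), g2)
  expect_error(select_reference_haplotype(mm2, "chr1"),
               "no all-homozygous F2")
})

test_that("phasing assigns haplotype labels consistent with simulated truth", {
  cfg <- sim_config(chrom_lengths = c(c1 = 4e6), marker_density = 2,
                    n_f2 = 12, mean_co_per_gamete = 0.3,
                    depth_mean = 10000, base_error = 0, geno_error = 0,
                    seed = 19)
  sim <- simulate_f2_population(cfg)
  mm <- filter_variants(sim$records, min_depth = 1, max_depth = 1e9)
  ph <- phase_population(mm)
  ref <- attr(ph, "ref_samples")[["c1"]]

  # the reference sample itself is one hap1 block with zero crossovers
  expect_true(all(ph[, ref] == "hap1"))
  ev_ref <- call_crossovers(genotype_blocks(mm$markers$pos, ph[, ref]))
  expect_equal(nrow(ev_ref), 0)

  # phased and unphased calling agree on event midpoints (each breakpoint
  # is a het<->hom switch; phasing only refines the hom side)
  unphased <- call_crossovers_all(mm)
  phased <- call_crossovers_all(mm, phased = ph)
  expect_equal(phased$events$midpoint, unphased$events$midpoint)
  expect_equal(phased$events$sample, unphased$events$sample)

  # phased labels match the simulated haplotype of origin up to the global
  # hap1/hap2 orientation of the reference
  tg <- sim$truth$genotypes
  starts <- sim$truth$phase_starts
  ref_hap <- starts$start_hap[starts$sample == ref & starts$gamete == 1]
  for (sn in setdiff(mm$samples, mm$f1)) {
    hom <- which(!is.na(tg[, sn]) & tg[, sn] != 1L)
    if (!length(hom)) next
    same_as_ref <- tg[hom, sn] == tg[hom, ref]
    expect_equal(unname(ph[hom, sn] == "hap1"), unname(same_as_ref))
  }
})

test_that("crossover midpoints are invariant to the reference haplotype choice", {
  # two complete all-hom samples carrying opposite haplotypes
  base <- c(rep(0L, 30), rep(2L, 30))
  g <- cbind(F1 = rep(1L, 60),
             a = rep(0L, 60),
             b = rep(2L, 60),
             x = c(rep(0L, 30), rep(1L, 30)),
             y = base)
  pos <- seq(0, by = 1000, length.out = 60)
  mm <- make_mm(pos, g)
  ph_a <- phase_intraspecific(mm, "chr1", "a")
  ph_b <- phase_intraspecific(mm, "chr1", "b")
  # labels swap...
  expect_true(all((ph_a == "hap1") == (ph_b == "hap2") |
                    ph_a == "het", na.rm = TRUE))
  # ...but events do not move
  for (sn in c("x", "y")) {
    ev_a <- suppressWarnings(call_crossovers(
      genotype_blocks(pos, ph_a[, sn], k = 10, min_span = 5000)))
    ev_b <- suppressWarnings(call_crossovers(
      genotype_blocks(pos, ph_b[, sn], k = 10, min_span = 5000)))
    expect_equal(ev_a$midpoint, ev_b$midpoint)
  }
})

test_that("interspecific genotyping labels F2 homozygotes by parental origin", {
  # parents reciprocally informative at most markers
  pa <- c(rep(0L, 50), 1L, 2L, NA)
  pb <- c(rep(2L, 50), 1L, 2L, 2L)
  f2 <- c(rep(0L, 20), rep(1L, 15), rep(2L, 15), 0L, 0L, 0L)
  g <- cbind(F1 = rep(1L, 53), P_A = pa, P_B = pb, s1 = f2)
  mm <- make_mm(seq(0, by = 1000, length.out = 53), g)
  lab <- genotype_interspecific(mm, "P_A", "P_B")
  expect_equal(unname(lab[1:20, "s1"]), rep("A_hom", 20))
  expect_equal(unname(lab[21:35, "s1"]), rep("het", 15))
  expect_equal(unname(lab[36:50, "s1"]), rep("B_hom", 15))
  # parent het, shared allele, or missing: marker dropped
  expect_true(all(is.na(lab[51:53, ])))
  expect_equal(attr(lab, "n_dropped"), 3L)
})

test_that("all-homozygous samples occur at about the expected rate", {
  lam <- 0.5
  cfg <- sim_config(chrom_lengths = c(c1 = 1e6), marker_density = 1,
                    n_f2 = 2000, mean_co_per_gamete = lam, depth_mean = 50,
                    seed = 55)
  sim <- simulate_f2_population(cfg)
  tg <- sim$truth$genotypes[, -1L]
  frac <- mean(apply(tg, 2L, function(g) all(g != 1L)))
  # P(no CO on either gamete) * P(same starting haplotype)
  p0 <- exp(-2 * lam) / 2
  expect_lt(abs(frac - p0), 0.03)
})
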