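test_that("CO-rate conversion and derived chromosome lengths are consistent", {
  len <- derive_chrom_lengths()
  expect_equal(sum(len), 225.418, tolerance = 1e-3)
  # genome-wide rates recomputed from mean CO counts and derived lengths
  expect_equal(round(co_rate(11.92, sum(len)), 2), 2.64)
  expect_equal(round(co_rate(9.47, sum(len)), 2), 2.10)
  expect_equal(co_rate(0, 100), 0)
  expect_error(co_rate(1, 0), "length_Mbp")
  # linearity
  expect_equal(co_rate(4, 10), 2 * co_rate(2, 10))
  # interspecific lengths derived from the same table agree chromosome-wise
  len_i <- derive_chrom_lengths(group = "inter")
  expect_equal(unname(len), unname(len_i), tolerance = 0.06)
})

test_that("window counting conserves events and uses half-open windows", {
  lens <- c(c1 = 2.2e6, c2 = 1e6)
  ev <- data.frame(chrom = c("c1", "c1", "c1", "c2"),
                   midpoint = c(0, 5e5, 2.15e6, 999999))
  w <- window_counts(ev, lens, size = 5e5)
  expect_equal(sum(w$co_count), 4)
  expect_equal(nrow(w), 5 + 2)
  # boundary midpoint 5e5 belongs to the right window (index 1)
  expect_equal(w$co_count[w$chrom == "c1" & w$win == 1], 1)
  expect_equal(w$co_count[w$chrom == "c1" & w$win == 0], 1)
  # truncated last window
  expect_equal(w$end[w$chrom == "c1" & w$win == 4], 2.2e6)
  expect_equal(w$co_count[w$chrom == "c1" & w$win == 4], 1)

  none <- window_counts(ev[0, ], lens, size = 5e5)
  expect_true(all(none$co_count == 0))
  bad <- data.frame(chrom = "c2", midpoint = 2e6)
  expect_error(window_counts(bad, lens), "beyond chromosome length")
})

test_that("windows with similar counts merge into count-conserving regions", {
  w <- data.frame(chrom = "c1", win = 0:4,
                  start = (0:4) * 5e5, end = (1:5) * 5e5,
                  co_count = c(3, 3, 3, 0, 0))
  r <- merge_similar(w, tol = 0)
  expect_equal(nrow(r), 2)
  expect_equal(r$observed, c(9, 0))
  expect_equal(r$n_windows, c(3, 2))
  expect_equal(sum(r$observed), sum(w$co_count))

  w2 <- transform(w, co_count = c(5, 4, 3, 2, 1))
  expect_equal(nrow(merge_similar(w2, tol = 0)), 5)
  r2 <- merge_similar(w2, tol = 1)
  expect_equal(sum(r2$observed), sum(w2$co_count))
  # regions never cross chromosomes
  w3 <- rbind(w, transform(w, chrom = "c2"))
  expect_true(all(table(merge_similar(w3, 0)$chrom) == 2))
})

test_that("randomization flags extreme regions at the resolution floor", {
  lens <- c(c1 = 5e6)
  ev <- withr::with_seed(2, data.frame(chrom = "c1",
                                       midpoint = runif(60, 2.0e6, 2.4e6)))
  w <- window_counts(ev, lens, size = 5e5)
  r <- merge_similar(w)
  rt <- randomization_test(r, lens, nrow(ev), n_rand = 999, seed = 3)
  hot <- rt[rt$observed == 60, ]
  expect_equal(hot$class, "hotspot")
  expect_equal(hot$p_hot, 1 / 1000)        # add-one floor
  # the empty remainder of the chromosome is a coldspot
  cold <- rt[rt$observed == 0 & rt$n_windows > 5, ]
  expect_true(all(cold$class == "coldspot"))
  expect_true(all(rt$p_hot > 0 & rt$p_hot <= 1 &
                    rt$p_cold > 0 & rt$p_cold <= 1))
})

test_that("region rates summarise the hotspot/coldspot contrast", {
  # rates engineered to the published group means: 8.04 and 0.48 cM/Mbp
  reg <- data.frame(chrom = "c1", start = c(0, 1e8, 2e8, 3e8),
                    end = c(1e8, 2e8, 3e8, 4e8),
                    n_windows = 1, observed = c(804, 804, 48, 48),
                    class = c("hotspot", "hotspot", "coldspot", "coldspot"))
  rr <- region_rates(reg, n_samples = 50)
  expect_equal(rr$summary$mean_hot, 8.04)
  expect_equal(rr$summary$mean_cold, 0.48)
  expect_equal(signif(rr$summary$ratio, 3), 16.8)

  # identical rates in both classes: ratio 1, t-test p 1
  reg2 <- transform(reg, observed = 100)
  rr2 <- region_rates(reg2, n_samples = 50)
  expect_equal(rr2$summary$ratio, 1)
  expect_equal(rr2$summary$t_p, 1)

  reg3 <- transform(reg, class = "neutral")
  expect_message(rr3 <- region_rates(reg3, 50), "summary unavailable")
  expect_true(is.na(rr3$summary$ratio))
})

test_that("windowed counts of uniform crossovers pass a goodness-of-fit check", {
  lens <- c(c1 = 1e7)
  ev <- withr::with_seed(23, uniform_events(2000, lens))
  w <- window_counts(ev, lens, size = 5e5)
  expect_equal(sum(w$co_count), 2000)
  p <- stats::chisq.test(w$co_count)$p.value
  expect_gt(p, 0.001)
})

test_that("Spearman wrapper matches the exhaustive-permutation oracle", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(4:6, 1)
      x <- sample(1000, n)
      y <- sample(1000, n)
      got <- spearman_test(x, y)
      want <- oracle_spearman(x, y)
      expect_equal(got$rho, want$rho, tolerance = 1e-12)
      expect_equal(got$p, want$p, tolerance = 1e-10)
      expect_true(got$exact)
    }
  })
  x <- 1:8
  expect_equal(spearman_test(x, x)$rho, 1)
  expect_equal(spearman_test(x, rev(x))$rho, -1)
  flagged <- spearman_test(rep(1, 5), 1:5)
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$rho))
  # ties fall back to the t-approximation
  expect_false(spearman_test(c(1, 1, 2, 3, 4), 1:5)$exact)
})

test_that("Brunner-Munzel test behaves on identical, shifted and simulated groups", {
  x <- c(1, 3, 5, 7, 9, 11)
  same <- brunner_munzel_test(x, x)
  expect_equal(same$estimate, 0.5)
  expect_gt(same$p, 0.9)

  shifted <- brunner_munzel_test(x, x + 100)
  expect_true(shifted$flagged || shifted$p < 1e-4)

  degenerate <- brunner_munzel_test(rep(1, 5), rep(1, 6))
  expect_true(degenerate$flagged)
  expect_equal(degenerate$estimate, 0.5)

  # agreement with a permutation oracle on study-sized groups
  withr::with_seed(61, {
    a <- rnorm(24, 2.64, 0.6)
    b <- rnorm(30, 2.10, 0.6)
    bm <- brunner_munzel_test(a, b)
    pool <- c(a, b)
    perm_p <- mean(replicate(4000, {
      idx <- sample(54, 24)
      abs(brunner_munzel_test(pool[idx], pool[-idx])$statistic) >=
        abs(bm$statistic) - 1e-12
    }))
    expect_lt(abs(bm$p - perm_p), 0.015)
  })
})

test_that("telomere and peri-centromere filtering is exact and idempotent", {
  lens <- c(c1 = 2.2e6, c2 = 1.5e6)
  ev <- data.frame(chrom = "c1", midpoint = 1)
  w <- window_counts(ev, lens, size = 5e5)
  tf <- telomere_centromere_filter(w, chrom_lengths = lens)
  expect_equal(nrow(w) - nrow(tf), 4)   # first and last window per chrom
  expect_identical(telomere_centromere_filter(tf, chrom_lengths = lens), tf)

  peri <- data.frame(chrom = "c2", start = 0, end = 1.5e6)
  pf <- telomere_centromere_filter(w, chrom_lengths = lens,
                                   pericentromere = peri,
                                   drop_telomeres = FALSE)
  expect_true(all(pf$chrom == "c1"))
  expect_identical(telomere_centromere_filter(pf, chrom_lengths = lens,
                                              pericentromere = peri,
                                              drop_telomeres = FALSE), pf)

  # any-bp overlap removes a window
  peri2 <- data.frame(chrom = "c1", start = 999999, end = 1000001)
  pf2 <- telomere_centromere_filter(w, pericentromere = peri2,
                                    drop_telomeres = FALSE)
  expect_equal(setdiff(w$win[w$chrom == "c1"], pf2$win[pf2$chrom == "c1"]),
               c(1, 2))
})

test_that("per-chromosome statistics reproduce the published-table layout", {
  lens <- c(a = 1e6, b = 2e6)
  ev <- data.frame(sample = rep(c("s1", "s2"), each = 3),
                   chrom = c("a", "a", "b", "a", "b", "b"))
  st <- chrom_stats(ev, n_samples = 2, chrom_lengths = lens)
  expect_equal(st$mean_co, c(1.5, 1.5, 3))
  expect_equal(st$chrom, c("a", "b", "All"))
  expect_equal(st$rate_cM_per_Mbp,
               co_rate(st$mean_co, st$length_Mbp))
})
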