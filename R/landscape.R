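#' Convert a mean crossover count per F2 into cM/Mbp
#'
#' An F2 carries two independent gametes, so the genetic map length in cM
#' is (mean_co / 2) * 100 and the rate is `mean_co * 50 / length_Mbp`.
#'
#' @param mean_co mean crossovers per F2 (two gametes).
#' @param length_Mbp physical length in Mbp (> 0).
#' @return Rate in cM per Mbp.
#' @export
#' @examples
#' co_rate(11.92, 225.42)   # ~2.64
co_rate <- function(mean_co, length_Mbp) {
  if (any(length_Mbp <= 0)) stop("length_Mbp must be > 0")
  mean_co * 50 / length_Mbp
}

#' Count crossover midpoints in fixed non-overlapping windows
#'
#' Windows are half-open `[i*size, (i+1)*size)`; the last window of each
#' chromosome is truncated. A midpoint exactly on a boundary belongs to the
#' right window; a midpoint equal to the chromosome length is kept in the
#' last window.
#'
#' @param events data frame with columns `chrom` and `midpoint` (or a
#'   position column named by `pos_col`).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param size window size in bp (default 500 kbp).
#' @param pos_col column holding the positions (default "midpoint").
#' @return Data frame `chrom, win, start, end, co_count` covering every
#'   window of every chromosome.
#' @export
window_counts <- function(events, chrom_lengths, size = 5e5,
                          pos_col = "midpoint") {
  stopifnot(size > 0)
  pos <- events[[pos_col]]
  lim <- chrom_lengths[events$chrom]
  if (any(is.na(lim)))
    stop("events on unknown chromosome(s): ",
         paste(unique(events$chrom[is.na(lim)]), collapse = ", "))
  if (any(pos < 0 | pos > lim))
    stop("event position beyond chromosome length (corrupt input)")
  out <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    n_win <- ceiling(len / size)
    p <- pos[events$chrom == cn]
    w <- pmin(floor(p / size), n_win - 1L)
    start <- (seq_len(n_win) - 1L) * size
    data.frame(chrom = cn, win = seq_len(n_win) - 1L, start = start,
               end = pmin(start + size, len),
               co_count = tabulate(w + 1L, nbins = n_win),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Merge adjacent windows with similar counts into regions
#'
#' Maximal runs of adjacent same-chromosome windows whose counts differ by
#' at most `tol` (pairwise within the run, i.e. max - min <= tol) become
#' one region whose observed count is the sum. The default `tol = 0` merges
#' only identical counts.
#'
#' @param windows data frame from [window_counts()].
#' @param tol non-negative count tolerance (default 0).
#' @return Data frame `chrom, start, end, n_windows, observed`.
#' @export
merge_similar <- function(windows, tol = 0) {
  stopifnot(tol >= 0)
  out <- lapply(unique(windows$chrom), function(cn) {
    w <- windows[windows$chrom == cn, , drop = FALSE]
    w <- w[order(w$win), , drop = FALSE]
    grp <- integer(nrow(w))
    g <- 1L
    run_min <- run_max <- w$co_count[1L]
    grp[1L] <- g
    for (i in seq_len(nrow(w))[-1L]) {
      lo <- min(run_min, w$co_count[i])
      hi <- max(run_max, w$co_count[i])
      if (hi - lo <= tol) {
        run_min <- lo; run_max <- hi
      } else {
        g <- g + 1L
        run_min <- run_max <- w$co_count[i]
      }
      grp[i] <- g
    }
    data.frame(chrom = cn,
               start = tapply(w$start, grp, min),
               end = tapply(w$end, grp, max),
               n_windows = as.integer(table(grp)),
               observed = as.integer(tapply(w$co_count, grp, sum)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Monte-Carlo hotspot/coldspot test by whole-genome event shuffling
#'
#' Each randomization re-places all `n_events` crossover midpoints
#' uniformly over the (unmasked) genome and counts them per region. With
#' the add-one correction, `p_hot = (1 + #\{rand >= obs\}) / (1 + n_rand)`
#' and `p_cold` analogously with `<=`. Regions with `p_hot < alpha` are
#' hotspots, `p_cold < alpha` coldspots; no multiple-testing correction is
#' applied.
#'
#' @param regions data frame from [merge_similar()].
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_events number of events to shuffle.
#' @param n_rand number of randomizations (default 10000).
#' @param seed optional RNG seed.
#' @param alpha per-region significance level (default 0.05).
#' @param mask optional data frame `chrom,start,end` excluded from
#'   placement (events land uniformly on the complement).
#' @return `regions` with added columns `expected, p_hot, p_cold, class`.
#' @export
randomization_test <- function(regions, chrom_lengths, n_events,
                               n_rand = 10000, seed = NULL, alpha = 0.05,
                               mask = NULL) {
  stopifnot(n_rand >= 1, n_events >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  chroms <- names(chrom_lengths)
  # placeable segments per chromosome (complement of the mask)
  segs <- lapply(chroms, function(cn) {
    len <- chrom_lengths[[cn]]
    if (is.null(mask)) return(data.frame(start = 0, end = len))
    m <- mask[mask$chrom == cn, , drop = FALSE]
    if (!nrow(m)) return(data.frame(start = 0, end = len))
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      cn, IRanges::IRanges(m$start + 1, m$end)))
    keep <- IRanges::gaps(IRanges::ranges(gr), start = 1L, end = len)
    data.frame(start = IRanges::start(keep) - 1, end = IRanges::end(keep))
  })
  names(segs) <- chroms
  seg_tab <- do.call(rbind, lapply(chroms, function(cn)
    cbind(chrom = cn, segs[[cn]], stringsAsFactors = FALSE)))
  seg_tab$width <- seg_tab$end - seg_tab$start
  total <- sum(seg_tab$width)
  if (total <= 0) stop("masked genome is empty")

  regions <- regions[order(match(regions$chrom, chroms), regions$start), ,
                     drop = FALSE]
  n_reg <- nrow(regions)
  # map a genomic position to its region id (regions tile each chromosome)
  reg_of <- function(chrom_idx, pos) {
    id <- integer(length(pos))
    for (ci in unique(chrom_idx)) {
      cn <- chroms[ci]
      sel <- chrom_idx == ci
      rsel <- which(regions$chrom == cn)
      id[sel] <- rsel[findInterval(pos[sel], regions$start[rsel])]
    }
    id
  }

  n_draw <- n_events * n_rand
  u <- stats::runif(n_draw, 0, total)
  cum <- cumsum(seg_tab$width)
  si <- findInterval(u, c(0, cum[-length(cum)]), left.open = FALSE)
  pos <- seg_tab$start[si] + (u - c(0, cum)[si])
  chrom_idx <- match(seg_tab$chrom[si], chroms)
  rid <- reg_of(chrom_idx, pos)
  counts <- matrix(tabulate(rid + n_reg * rep(0:(n_rand - 1L),
                                              each = n_events),
                            nbins = n_reg * n_rand), nrow = n_reg)
  obs <- regions$observed
  regions$expected <- rowMeans(counts)
  regions$p_hot <- (1 + rowSums(counts >= obs)) / (1 + n_rand)
  regions$p_cold <- (1 + rowSums(counts <= obs)) / (1 + n_rand)
  regions$class <- "neutral"
  regions$class[regions$p_hot < alpha] <- "hotspot"
  regions$class[regions$p_cold < alpha] <- "coldspot"
  regions
}

#' Per-region CO rates and hotspot/coldspot summary
#'
#' Computes each region's recombination rate via [co_rate()] applied to the
#' regional mean CO count per F2 and the regional span in Mbp, then
#' summarises classified regions: mean hotspot rate, mean coldspot rate,
#' their ratio, and a Welch two-sample t-test across region rates.
#'
#' @param regions classified regions from [randomization_test()].
#' @param n_samples number of F2 samples the counts were pooled over.
#' @return List `regions` (with `rate_cM_per_Mbp` added) and `summary`
#'   (`mean_hot, mean_cold, ratio, t_p`; fields are `NA` with a message
#'   when either class is absent).
#' @export
region_rates <- function(regions, n_samples) {
  span_mbp <- (regions$end - regions$start) / 1e6
  regions$rate_cM_per_Mbp <- co_rate(regions$observed / n_samples, span_mbp)
  hot <- regions$rate_cM_per_Mbp[regions$class == "hotspot"]
  cold <- regions$rate_cM_per_Mbp[regions$class == "coldspot"]
  if (!length(hot) || !length(cold)) {
    message("no ", if (!length(hot)) "hotspot" else "coldspot",
            " regions; summary unavailable")
    summary <- list(mean_hot = NA_real_, mean_cold = NA_real_,
                    ratio = NA_real_, t_p = NA_real_)
  } else {
    t_p <- if (stats::sd(c(hot, cold)) == 0) 1 else
      if (length(hot) > 1L && length(cold) > 1L)
        tryCatch(stats::t.test(hot, cold)$p.value,
                 error = function(e) NA_real_) else NA_real_
    summary <- list(mean_hot = mean(hot), mean_cold = mean(cold),
                    ratio = mean(hot) / mean(cold), t_p = t_p)
  }
  list(regions = regions, summary = summary)
}

#' Per-chromosome crossover statistics
#'
#' Mean crossovers per F2 and the corresponding rate in cM/Mbp for each
#' chromosome and genome-wide.
#'
#' @param events events data frame (columns `sample`, `chrom`).
#' @param n_samples number of F2 samples.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @return Data frame `chrom, mean_co, length_Mbp, rate_cM_per_Mbp` with a
#'   final row `All` for the whole genome.
#' @export
chrom_stats <- function(events, n_samples, chrom_lengths) {
  chroms <- names(chrom_lengths)
  n_co <- vapply(chroms, function(cn) sum(events$chrom == cn), numeric(1))
  len <- chrom_lengths / 1e6
  df <- data.frame(chrom = c(chroms, "All"),
                   mean_co = c(n_co, sum(n_co)) / n_samples,
                   length_Mbp = c(len, sum(len)),
                   stringsAsFactors = FALSE, row.names = NULL)
  df$rate_cM_per_Mbp <- co_rate(df$mean_co, df$length_Mbp)
  df
}

#' Drop telomeric and/or peri-centromeric windows
#'
#' Telomeric windows are the first and last window of each chromosome.
#' Peri-centromeric windows are those overlapping (by any bp) an interval
#' of the supplied table. The operation is idempotent.
#'
#' @param windows data frame from [window_counts()].
#' @param chrom_lengths named vector of chromosome lengths (bp); required
#'   for telomere dropping so the operation stays idempotent (the last
#'   window is recognised by its end coordinate, not by rank).
#' @param pericentromere optional data frame `chrom,start,end` (0-based
#'   half-open).
#' @param drop_telomeres drop first/last windows (default TRUE).
#' @return Filtered windows data frame.
#' @export
telomere_centromere_filter <- function(windows, chrom_lengths = NULL,
                                       pericentromere = NULL,
                                       drop_telomeres = TRUE) {
  keep <- rep(TRUE, nrow(windows))
  if (drop_telomeres) {
    if (is.null(chrom_lengths))
      stop("chrom_lengths is required to identify telomeric windows")
    keep[windows$win == 0L |
           windows$end >= chrom_lengths[windows$chrom]] <- FALSE
  }
  if (!is.null(pericentromere)) {
    for (i in seq_len(nrow(pericentromere))) {
      keep[windows$chrom == pericentromere$chrom[i] &
             windows$start < pericentromere$end[i] &
             windows$end > pericentromere$start[i]] <- FALSE
    }
  }
  windows[keep, , drop = FALSE]
}
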