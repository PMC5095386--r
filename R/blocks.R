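#' Find seeds: long unambiguous runs of one genotype
#'
#' A seed is a maximal run of at least `k` consecutive same-label markers
#' whose physical span (last minus first position) is strictly greater than
#' `min_span`. Runs failing either criterion are left unassigned and may be
#' absorbed later by merging or extension. Missing calls must be removed
#' before calling (they are transparent to run-length counting).
#'
#' @param pos sorted marker positions (bp).
#' @param label genotype label per marker (no `NA`).
#' @param k minimum run length in markers (default 25).
#' @param min_span minimum bp span, strict (default 10000).
#' @return Data frame `start, end, label` (marker indices, inclusive).
#' @export
find_seeds <- function(pos, label, k = 25, min_span = 10000) {
  stopifnot(k >= 2, min_span > 0, length(pos) == length(label))
  if (!length(pos)) return(data.frame(start = integer(), end = integer(),
                                      label = character()))
  if (anyNA(label)) stop("labels must not contain NA (drop MISSING first)")
  r <- rle(label)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  ok <- r$lengths >= k & (pos[end] - pos[start]) > min_span
  data.frame(start = start[ok], end = end[ok], label = r$values[ok],
             stringsAsFactors = FALSE)
}

#' Merge adjacent same-genotype seeds into blocks
#'
#' Consecutive seeds sharing a label, with no differently-labelled seed
#' between them, fuse into one block that absorbs the intervening unassigned
#' markers; absorbed markers that disagree with the block label are counted
#' in `n_mismatch`. The resulting blocks alternate labels.
#'
#' @param seeds data frame from [find_seeds()] (ordered).
#' @param label full label vector of the sequence.
#' @return Data frame `start, end, label, n_markers, n_mismatch`.
#' @export
merge_seeds <- function(seeds, label) {
  if (nrow(seeds) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      label = character(), n_markers = integer(),
                      n_mismatch = integer()))
  grp <- cumsum(c(TRUE, seeds$label[-1L] != seeds$label[-nrow(seeds)]))
  start <- tapply(seeds$start, grp, min)
  end <- tapply(seeds$end, grp, max)
  lab <- tapply(seeds$label, grp, `[`, 1L)
  mism <- mapply(function(s, e, L) sum(label[s:e] != L), start, end, lab)
  data.frame(start = as.integer(start), end = as.integer(end),
             label = as.character(lab),
             n_markers = as.integer(end - start + 1L),
             n_mismatch = as.integer(mism), stringsAsFactors = FALSE,
             row.names = NULL)
}

# furthest prefix length t (0..m) at which the cumulative
# match-minus-mismatch score attains its maximum; t = 0 means no extension
walk_extend <- function(gap_labels, block_label) {
  m <- length(gap_labels)
  if (!m) return(0L)
  cs <- cumsum(ifelse(gap_labels == block_label, 1L, -1L))
  top <- max(0L, max(cs))
  cand <- which(cs == top)
  if (!length(cand)) return(0L)
  max(cand)
}

#' Extend blocks over unassigned markers
#'
#' Each block edge walks outward over the unassigned markers toward its
#' neighbour, maintaining a cumulative score of (+1) per matching and (-1)
#' per non-matching marker; the new boundary is the furthest matching
#' marker at which the cumulative score attains its maximum (ties go to the
#' furthest — the operational reading of extension "until the proportion of
#' the genotype starts to decline"). Both blocks flanking a gap extend
#' independently; if their extensions overlap, the boundary is placed at
#' the split maximizing the sum of both scores (ties split at the midpoint
#' marker).
#'
#' @param blocks data frame from [merge_seeds()].
#' @param label full label vector of the sequence.
#' @return Updated blocks data frame (same columns).
#' @export
extend_blocks <- function(blocks, label) {
  n <- nrow(blocks)
  if (n == 0L) return(blocks)
  # leading gap: first block extends leftward
  lead <- seq_len(blocks$start[1L] - 1L)
  if (length(lead)) {
    t <- walk_extend(rev(label[lead]), blocks$label[1L])
    blocks$start[1L] <- blocks$start[1L] - t
  }
  # trailing gap: last block extends rightward
  if (blocks$end[n] < length(label)) {
    trail <- seq.int(blocks$end[n] + 1L, length(label))
    t <- walk_extend(label[trail], blocks$label[n])
    blocks$end[n] <- blocks$end[n] + t
  }
  if (n > 1L) for (i in seq_len(n - 1L)) {
    lo <- blocks$end[i] + 1L
    hi <- blocks$start[i + 1L] - 1L
    if (lo > hi) next
    g <- label[lo:hi]
    m <- length(g)
    tL <- walk_extend(g, blocks$label[i])
    tR <- walk_extend(rev(g), blocks$label[i + 1L])
    if (tL + tR > m) {
      # overlapping extensions: maximize the sum of both cumulative scores
      sL <- c(0L, cumsum(ifelse(g == blocks$label[i], 1L, -1L)))
      sRr <- c(0L, cumsum(ifelse(rev(g) == blocks$label[i + 1L], 1L, -1L)))
      total <- sL + rev(sRr)          # split after c absorbed by left
      cand <- which(total == max(total)) - 1L
      c_star <- cand[which.min(abs(cand - m / 2))]
      tL <- c_star
      tR <- m - c_star
    }
    blocks$end[i] <- blocks$end[i] + tL
    blocks$start[i + 1L] <- blocks$start[i + 1L] - tR
  }
  blocks$n_markers <- blocks$end - blocks$start + 1L
  blocks$n_mismatch <- vapply(seq_len(n), function(i)
    sum(label[blocks$start[i]:blocks$end[i]] != blocks$label[i]),
    integer(1))
  blocks
}

#' Segment one genotype sequence into blocks
#'
#' Convenience wrapper running [find_seeds()], [merge_seeds()] and
#' [extend_blocks()] on one sample-chromosome genotype sequence. Missing
#' labels (`NA`) are transparent: they are dropped before run-length
#' counting and never break a run.
#'
#' @param pos sorted marker positions.
#' @param label genotype label per marker (`NA` allowed, skipped).
#' @param k,min_span seeding thresholds, see [find_seeds()].
#' @return Data frame of blocks with marker-index (`start`, `end` into the
#'   informative subsequence) and bp (`start_pos`, `end_pos`) bounds.
#' @export
genotype_blocks <- function(pos, label, k = 25, min_span = 10000) {
  keep <- !is.na(label)
  pos <- pos[keep]
  label <- label[keep]
  blocks <- extend_blocks(merge_seeds(find_seeds(pos, label, k, min_span),
                                      label), label)
  blocks$start_pos <- pos[blocks$start]
  blocks$end_pos <- pos[blocks$end]
  blocks
}

#' Call crossover events from adjacent block boundaries
#'
#' One crossover is called at each adjacency of two blocks with different
#' labels: the event interval runs from the last marker of the upstream
#' block to the first marker of the downstream block and is summarised by
#' its midpoint. An adjacency of two opposite homozygous blocks would
#' require two simultaneous crossovers between two adjacent markers; it is
#' emitted as two events at the same interval, with a warning.
#'
#' @param blocks block data frame from [genotype_blocks()].
#' @param het_label label regarded as heterozygous (default "het").
#' @return Data frame `left, right, midpoint, from, to, resolution`.
#' @export
call_crossovers <- function(blocks, het_label = "het") {
  n <- nrow(blocks)
  empty <- data.frame(left = numeric(), right = numeric(),
                      midpoint = numeric(), from = character(),
                      to = character(), resolution = numeric())
  if (n < 2L) return(empty)
  i <- seq_len(n - 1L)
  ev <- data.frame(left = blocks$end_pos[i], right = blocks$start_pos[i + 1L],
                   from = blocks$label[i], to = blocks$label[i + 1L],
                   stringsAsFactors = FALSE)
  double <- ev$from != het_label & ev$to != het_label
  if (any(double)) {
    warning(sum(double), " opposite-homozygote adjacency(ies): ",
            "counted as two coincident crossovers")
    ev <- ev[rep(seq_len(nrow(ev)), times = 1L + double), , drop = FALSE]
  }
  ev$midpoint <- floor((ev$left + ev$right) / 2)
  ev$resolution <- ev$right - ev$left
  rownames(ev) <- NULL
  ev[, c("left", "right", "midpoint", "from", "to", "resolution")]
}

#' Segment every F2 of a marker matrix and call all crossovers
#'
#' Runs block segmentation and crossover calling per F2 sample per
#' chromosome. Without `phased` labels, intraspecific two-state labels are
#' derived from the genotype codes (`hom`/`het`); with a phased (or
#' interspecific) label matrix, its three-state labels are used instead.
#'
#' @param matrix_obj a `marker_matrix` from [filter_variants()].
#' @param phased optional character label matrix (markers x samples), e.g.
#'   from [phase_population()] or [genotype_interspecific()].
#' @param k,min_span seeding thresholds, see [find_seeds()].
#' @param samples samples to process (default: all but the F1).
#' @return List with data frames `blocks` (`sample, chrom, start_pos,
#'   end_pos, label, n_markers, n_mismatch`) and `events` (`sample, chrom,
#'   left, right, midpoint, from, to, resolution`).
#' @export
call_crossovers_all <- function(matrix_obj, phased = NULL, k = 25,
                                min_span = 10000,
                                samples = setdiff(matrix_obj$samples,
                                                  matrix_obj$f1)) {
  stopifnot(inherits(matrix_obj, "marker_matrix"))
  blocks_out <- list()
  events_out <- list()
  for (cn in unique(matrix_obj$markers$chrom)) {
    idx <- which(matrix_obj$markers$chrom == cn)
    pos <- matrix_obj$markers$pos[idx]
    for (sn in samples) {
      if (is.null(phased)) {
        g <- matrix_obj$geno[idx, sn]
        lab <- c("hom", "het", "hom")[g + 1L]
      } else {
        lab <- phased[idx, sn]
      }
      bl <- genotype_blocks(pos, lab, k, min_span)
      if (nrow(bl)) {
        blocks_out[[length(blocks_out) + 1L]] <- cbind(
          data.frame(sample = sn, chrom = cn, stringsAsFactors = FALSE),
          bl[, c("start_pos", "end_pos", "label", "n_markers",
                 "n_mismatch")])
        ev <- call_crossovers(bl)
        if (nrow(ev))
          events_out[[length(events_out) + 1L]] <- cbind(
            data.frame(sample = sn, chrom = cn, stringsAsFactors = FALSE),
            ev)
      }
    }
  }
  list(
    blocks = if (length(blocks_out)) do.call(rbind, blocks_out) else NULL,
    events = if (length(events_out)) do.call(rbind, events_out) else
      data.frame(sample = character(), chrom = character(),
                 left = numeric(), right = numeric(), midpoint = numeric(),
                 from = character(), to = character(),
                 resolution = numeric())
  )
}
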