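#' Run the full crossover-landscape pipeline on a simulated cross
#'
#' Orchestrates simulate -> filter -> (phase) -> block/crossover calling ->
#' windowed landscape with randomization -> mutation coupling into one
#' reproducible run with a machine-readable report. Inputs are either a
#' [sim_config()] (simulation mode) or a VCF path plus chromosome-length
#' table (data mode).
#'
#' @param config list with elements:
#'   * `sim`: a [sim_config()] (simulation mode), or
#'   * `vcf`, `chrom_lengths_file`, `f1`: input paths (data mode);
#'   * `sv_file`: optional SV interval table for masking;
#'   * `window_size` (default 5e5), `n_rand` (default 10000),
#'     `merge_tol` (default 0), `alpha` (default 0.05),
#'     `seed` (default 1), `phased` (logical, default FALSE: call
#'     crossovers on hom/het labels), `coupling_radius` (default 2000).
#' @param out optional directory; when given, tabular outputs (TSV/BED)
#'   and the JSON report are written there.
#' @return The report as a list (invisibly written as JSON when `out` is
#'   given): per-chromosome stats, classified regions, hotspot/coldspot
#'   summary, coupling results when mutations exist, truth-evaluation when
#'   simulated, and provenance (seed, package version, config hash).
#' @export
run_pipeline <- function(config, out = NULL) {
  defaults <- list(window_size = 5e5, n_rand = 10000, merge_tol = 0,
                   alpha = 0.05, seed = 1L, phased = FALSE,
                   coupling_radius = 2000)
  config <- utils::modifyList(defaults, config)

  truth <- NULL
  mutations <- NULL
  if (!is.null(config$sim)) {
    sim <- simulate_f2_population(config$sim)
    records <- sim$records
    truth <- sim$truth
    chrom_lengths <- config$sim$chrom_lengths
    if (config$sim$mutation_rate > 0)
      mutations <- inject_mutations(config$sim, truth)
  } else {
    for (field in c("vcf", "chrom_lengths_file")) {
      if (is.null(config[[field]]))
        stop("config field '", field, "' is required in data mode")
      if (!file.exists(config[[field]]))
        stop("config field '", field, "': file not found: ",
             config[[field]])
    }
    records <- read_marker_vcf(config$vcf, f1 = config$f1 %||% "F1")
    chrom_lengths <- read_chrom_lengths(config$chrom_lengths_file)
  }

  mm <- filter_variants(records)
  if (!is.null(config$sv_file)) {
    if (!file.exists(config$sv_file))
      stop("config field 'sv_file': file not found: ", config$sv_file)
    mask <- build_sv_mask(read_intervals(config$sv_file), chrom_lengths)
    mm <- apply_mask(mm, mask)
  }

  phased <- if (isTRUE(config$phased)) phase_population(mm) else NULL
  calls <- call_crossovers_all(mm, phased = phased)
  events <- calls$events
  n_f2 <- length(setdiff(mm$samples, mm$f1))

  stats_tab <- chrom_stats(events, n_f2, chrom_lengths)
  windows <- window_counts(events, chrom_lengths, config$window_size)
  regions <- merge_similar(windows, config$merge_tol)
  regions <- randomization_test(regions, chrom_lengths, nrow(events),
                                n_rand = config$n_rand,
                                seed = config$seed + 10L,
                                alpha = config$alpha)
  rr <- region_rates(regions, n_f2)

  report <- list(
    n_markers = nrow(mm$markers),
    n_events = nrow(events),
    chrom_stats = stats_tab,
    regions = rr$regions,
    hotspot_coldspot = rr$summary,
    provenance = list(seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("coscape")),
                      n_rand = config$n_rand,
                      window_size = config$window_size)
  )
  if (!is.null(mutations) && nrow(mutations) > 0 && nrow(events) > 0) {
    report$coupling <- proximity_enrichment_test(
      mutations, events, chrom_lengths, radius = config$coupling_radius,
      n_rand = min(config$n_rand, 1000), seed = config$seed + 11L)
    report$binned_coupling <- binned_correlation(mutations, events,
                                                 chrom_lengths)
  }
  if (!is.null(truth))
    report$truth_evaluation <- evaluate_co_calls(events, truth)
  report$provenance$config_hash <- report_hash(report)

  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    utils::write.table(events, file.path(out, "events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(windows, file.path(out, "windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(rr$regions, file.path(out, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic md5 of a report, via its canonical JSON rendering
report_hash <- function(report) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(report, tf, auto_unbox = TRUE, digits = 12,
                       dataframe = "rows", force = TRUE)
  unname(tools::md5sum(tf))
}

#' Build the bundled small simulated fixture
#'
#' A deterministic two-chromosome, ten-F2 simulated cross with truth,
#' small enough for tests and documentation examples: 12 and 8 Mbp
#' chromosomes at 1.5 markers/kbp, mean depth 50x, base error 0.01,
#' genotyping error 0.001, ~0.75 crossovers per gamete per chromosome,
#' and three de novo mutations per F2 genome on average.
#'
#' @param seed RNG seed (default 20).
#' @param dir optional directory; when given, [write_sim_outputs()] writes
#'   the VCF and truth tables there.
#' @return List `sim` (a `sim_result`), `mutations`, `config`.
#' @export
make_fixture <- function(seed = 20L, dir = NULL) {
  config <- sim_config(
    chrom_lengths = c(chr1 = 12e6, chr2 = 8e6),
    marker_density = 1.5, n_f2 = 10, mean_co_per_gamete = 0.75,
    depth_mean = 50, base_error = 0.01, geno_error = 0.001,
    mutation_rate = 3, seed = seed)
  sim <- simulate_f2_population(config)
  mutations <- inject_mutations(config, sim$truth)
  if (!is.null(dir)) write_sim_outputs(sim, dir, mutations)
  list(sim = sim, mutations = mutations, config = config)
}
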