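# End-to-end survey driver: executes the stages for which inputs are
# available (stats -> ssr -> mask -> sre -> gc -> map), writes per-stage
# tables plus a human-readable report, and a machine-readable manifest.
# Stage outputs are pure functions of (inputs, config, seed).

#' Survey configuration
#'
#' Stage thresholds default to the survey's standard values: SSRs of
#' period 1-3 need 12 nt and periods 4-6 need 4 units; self-comparison
#' uses a 100 bp window at 90% identity under E <= 1e-50 with support >= 6;
#' mapping filters at 75% identity, E < 1e-20, coverage > 50% and pairs
#' within 500 kb.
#'
#' @param genome_size haploid genome size (bases); required for SRE
#'   extrapolation.
#' @param ssr,self_compare,sre,mapping,repeat_filter stage parameter lists
#'   (partial overrides are merged over the defaults).
#' @param seed integer seed for any stage randomness.
#' @return list of class "survey_config".
#' @export
survey_config <- function(genome_size, ssr = list(), self_compare = list(),
                          sre = list(), mapping = list(),
                          repeat_filter = list(), seed = 1L) {
  merge_defaults <- function(user, def) {
    def[names(user)] <- user
    def
  }
  structure(list(
    genome_size = genome_size,
    ssr = merge_defaults(ssr, list(min_len_short = 12L,
                                   min_units_long = 4L)),
    self_compare = merge_defaults(self_compare,
                                  list(window = 100L, min_identity = 90,
                                       max_evalue = 1e-50)),
    sre = merge_defaults(sre, list(min_support = 6L)),
    mapping = merge_defaults(mapping,
                             list(min_identity = 75, max_evalue = 1e-20,
                                  min_coverage = 0.5, max_insert = 5e5)),
    repeat_filter = merge_defaults(repeat_filter,
                                   list(min_identity = 70,
                                        min_length = 50)),
    seed = as.integer(seed)), class = "survey_config")
}

fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)

#' Run the BES survey
#'
#' Executes every stage whose inputs are present; missing inputs skip the
#' stage with a logged reason.  All output files land in \code{out_dir}.
#'
#' @param reads named character vector of BES reads (or a FASTA path).
#' @param config a [survey_config()].
#' @param out_dir output directory (created if needed).
#' @param repeat_library repeat library data.frame (or FASTA path) for the
#'   masking stage.
#' @param library_metadata optional data.frame (library_id, clone_count,
#'   mean_insert, empty_fraction, organellar_fraction) for the stats
#'   stage.
#' @param screens optional data.frame (probe_set, positives,
#'   clones_screened) of hybridization screens.
#' @param signatures optional protein-signature interval table (read_id,
#'   start, end) for the GC stage.
#' @param reference optional named character vector of reference sequences
#'   for the mapping stage.
#' @param annotation optional GRanges (or GFF3 path) of reference coding
#'   features.
#' @param verbose log stage progress to stderr.
#' @return invisible list of stage results; files in \code{out_dir}.
#' @export
run_survey <- function(reads, config, out_dir,
                       repeat_library = NULL, library_metadata = NULL,
                       screens = NULL, signatures = NULL,
                       reference = NULL, annotation = NULL,
                       verbose = TRUE) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fasta(reads)
  if (is.character(repeat_library) && length(repeat_library) == 1)
    repeat_library <- read_repeat_library(repeat_library)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (verbose)
    message(format(Sys.time(), "[%H:%M:%S] "), ...)
  set.seed(config$seed)
  results <- list()
  rpt <- c("BES survey report", "=================", "")
  corpus_bases <- sum(nchar(reads))
  records <- bes_records(reads)
  pairing <- pair_bes(records)
  rpt <- c(rpt, sprintf("Reads: %d (%d bases); paired: %s%%",
                        length(reads), corpus_bases,
                        fmt(pairing$paired_fraction, 1)), "")

  # -- stats ---------------------------------------------------------------
  if (!is.null(library_metadata)) {
    log_stage("stats: library coverage")
    lm <- library_metadata
    cov <- coverage_report(lm$clone_count, lm$mean_insert,
                           lm$empty_fraction, lm$organellar_fraction,
                           config$genome_size)
    stats_tbl <- data.frame(
      library_id = lm$library_id,
      genome_equivalents = round_half_up(cov$genome_equivalents, 2),
      genome_equivalents_rounded = cov$genome_equivalents_rounded)
    write.table(stats_tbl, file.path(out_dir, "library_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    rpt <- c(rpt, "Library coverage",
             sprintf("  %s: %sX (%s exact)", lm$library_id,
                     fmt(cov$genome_equivalents_rounded, 0),
                     fmt(cov$genome_equivalents, 2)),
             sprintf("  P(find locus, combined) = %s%%",
                     fmt(100 * cov$p_find, 4)), "")
    results$stats <- cov
    if (!is.null(screens)) {
      rates <- contamination_rate(screens$positives,
                                  screens$clones_screened)
      rpt <- c(rpt, "Contamination screens",
               sprintf("  %s: %s%%", screens$probe_set, fmt(rates, 2)), "")
      results$contamination <- setNames(rates, screens$probe_set)
    }
  } else log_stage("stats: skipped (no library metadata)")

  # -- ssr -----------------------------------------------------------------
  log_stage("ssr: scanning ", length(reads), " reads")
  loci <- find_ssrs(reads, config$ssr$min_len_short,
                    config$ssr$min_units_long)
  ssr_sum <- summarize_ssrs(loci, corpus_bases)
  write.table(loci, file.path(out_dir, "ssr_loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rpt <- c(rpt, "SSRs",
           sprintf("  loci: %d (%d bases)", ssr_sum$total_count,
                   ssr_sum$total_bases_in_ssrs),
           sprintf("  density: one SSR per %s kb",
                   fmt(ssr_sum$density_kb_per_ssr, 1)),
           sprintf("  loci > 20 nt: %d", ssr_sum$count_over_cutoff),
           sprintf("  by period: %s",
                   paste(sprintf("%s:%d", names(ssr_sum$by_period),
                                 as.integer(ssr_sum$by_period)),
                         collapse = " ")), "")
  results$ssr <- ssr_sum

  # -- mask ----------------------------------------------------------------
  masked <- reads
  if (!is.null(repeat_library)) {
    log_stage("mask: annotating against ", nrow(repeat_library),
              " library entries")
    ann <- annotate_repeats(reads, repeat_library,
                            min_identity = config$repeat_filter$min_identity,
                            min_length = config$repeat_filter$min_length)
    masked <- ann$masked
    lc <- detect_low_complexity(reads)
    rsum <- summarize_repeats(ann$hits, corpus_bases, lc)
    write.table(rsum, file.path(out_dir, "repeat_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_fasta(masked, file.path(out_dir, "masked_reads.fasta"))
    inter <- attr(rsum, "interspersed")
    rpt <- c(rpt, "Known repeats",
             sprintf("  elements: %d", sum(ann$hits$merged_from >= 1)),
             sprintf("  interspersed repeat bases: %d (%s%%)",
                     as.integer(inter$bases), fmt(inter$pct, 2)), "")
    results$repeats <- list(hits = ann$hits, summary = rsum)
  } else log_stage("mask: skipped (no repeat library)")

  # -- sre -----------------------------------------------------------------
  log_stage("sre: self-comparison")
  sre <- mine_sres(masked, config$genome_size,
                   min_support = config$sre$min_support,
                   window = config$self_compare$window,
                   min_identity = config$self_compare$min_identity,
                   max_evalue = config$self_compare$max_evalue,
                   nt_databases = if (!is.null(repeat_library))
                     list(setNames(repeat_library$sequence,
                                   repeat_library$name)) else list())
  if (nrow(sre$catalog) > 0)
    write.table(sre$catalog[, c("sre_id", "length", "support",
                                "genome_copies_est")],
                file.path(out_dir, "sre_catalog.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  matched <- sum(sre$profile$counts > 0)
  rpt <- c(rpt, "Novel repeats (SREs)",
           sprintf("  reads matching another read: %d (%s%%)", matched,
                   fmt(100 * matched / length(reads), 1)),
           sprintf("  candidate families: %d; retained: %d",
                   nrow(sre$candidates), nrow(sre$catalog)),
           if (nrow(sre$catalog) > 0)
             sprintf("  top family support %d -> ~%d genome copies",
                     max(sre$catalog$support),
                     max(sre$catalog$genome_copies_est)), "")
  results$sre <- sre

  # -- gc ------------------------------------------------------------------
  log_stage("gc: partitioning")
  if (!is.null(signatures)) {
    gc <- partition_gc(reads, signatures)
    rpt <- c(rpt, "GC partition",
             sprintf("  overall %s%%; coding %s%% (%d bases); non-coding %s%% (%d bases)",
                     fmt(gc$overall_gc, 1), fmt(gc$coding_gc, 1),
                     gc$coding_bases, fmt(gc$noncoding_gc, 1),
                     gc$noncoding_bases),
             sprintf("  reads with protein signature: %s%%",
                     fmt(gc$signature_fraction, 1)), "")
    results$gc <- gc
  } else {
    overall <- gc_content_total(reads)
    rpt <- c(rpt, "GC content",
             sprintf("  overall %s%% (no signature intervals provided)",
                     fmt(overall, 1)), "")
    results$gc <- list(overall_gc = overall)
  }

  # -- map -----------------------------------------------------------------
  if (!is.null(reference)) {
    log_stage("map: placing reads on ", length(reference),
              " reference sequence(s)")
    hits <- map_reads_nt(reads, reference)
    lens <- setNames(nchar(reads), names(reads))
    passing <- filter_hits(hits, lens, config$mapping$min_identity,
                           config$mapping$max_evalue,
                           config$mapping$min_coverage)
    placements <- best_placement(passing)
    called <- call_pairs(placements, pairing$pairs,
                         config$mapping$max_insert)
    write.table(placements[, BLAST6_COLS],
                file.path(out_dir, "placements.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rpt <- c(rpt, "Comparative mapping",
             sprintf("  placed reads: %d of %d", nrow(placements),
                     length(reads)),
             sprintf("  paired clones: %d; high-scoring singlets: %d",
                     nrow(called$pairs), length(called$singlets)))
    if (!is.null(annotation)) {
      cod <- coding_overlap(placements, annotation)
      rpt <- c(rpt, sprintf("  placements in coding sequence: %s%%",
                            fmt(cod, 2)))
    }
    rpt <- c(rpt, "")
    results$mapping <- list(placements = placements, pairs = called)
  } else log_stage("map: skipped (no reference)")

  writeLines(rpt, file.path(out_dir, "report.txt"))
  manifest <- list(seed = config$seed, genome_size = config$genome_size,
                   reads = length(reads), corpus_bases = corpus_bases,
                   stages_run = names(results))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
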