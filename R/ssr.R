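# Simple sequence repeat (microsatellite) detection: maximal perfect tandem
# repeats with primitive period 1-6.  Period classes 1-3 must reach a total
# length threshold (default 12 nt); classes 4-6 must reach a unit-count
# threshold (default 4 units); fractional trailing units count toward the
# locus length.  N breaks a run.

#' Find perfect SSRs in sequences
#'
#' @param seqs named character vector of sequences (uppercase; lowercase is
#'   uppercased before scanning).
#' @param min_len_short minimum total length for periods 1-3 (nt).
#' @param min_units_long minimum unit count for periods 4-6.
#' @return data.frame with read_id, start, end (1-based inclusive), period,
#'   motif (first-occurring phase), length, unit_count.
#' @export
find_ssrs <- function(seqs, min_len_short = 12L, min_units_long = 4L) {
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  out <- lapply(names(seqs), function(id) {
    df <- cpp_find_ssrs(toupper(seqs[[id]]), min_len_short, min_units_long)
    if (nrow(df) == 0) return(NULL)
    df$read_id <- id
    df
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(), period = integer(),
                      motif = character(), read_id = character(),
                      stringsAsFactors = FALSE)
  out$length <- out$end - out$start + 1L
  out$unit_count <- out$length / out$period
  out[, c("read_id", "start", "end", "period", "motif", "length",
          "unit_count")]
}

#' Canonical motif class
#'
#' A motif and its reverse complement are tabulated together; the class
#' label joins the lexicographically smaller member first ("GCC/GGC").
#' Rotations are kept distinct, so GCC/GGC and CGC/GCG are separate classes.
#'
#' @param motif character vector of primitive motifs (1-6 nt).
#' @return character vector of class labels.
#' @export
canonical_motif_class <- function(motif) {
  vapply(motif, function(m) {
    m <- toupper(m)
    if (nchar(m) < 1 || nchar(m) > 6) stop("motif length must be 1-6")
    if (!is_primitive_motif(m)) stop("motif '", m, "' is not primitive")
    rc <- revcomp(m)
    pair <- sort(c(m, rc), method = "radix")
    if (m == rc) paste(m, m, sep = "/") else paste(pair[1], pair[2], sep = "/")
  }, character(1), USE.NAMES = FALSE)
}

is_primitive_motif <- function(m) {
  p <- nchar(m)
  if (p == 1) return(TRUE)
  for (d in seq_len(p - 1)) {
    if (p %% d != 0) next
    if (m == strrep(substr(m, 1, d), p / d)) return(FALSE)
  }
  TRUE
}

#' Summarize an SSR catalog
#'
#' @param loci SSR table from [find_ssrs()].
#' @param total_bases total bases of the corpus the loci came from
#'   (including masked/N bases; this is the density denominator).
#' @param long_cutoff loci longer than this many nt are counted separately
#'   (marker-grade SSRs).
#' @return list with total_count, total_bases_in_ssrs, density_kb_per_ssr
#'   (1 decimal; NA when there are no loci), counts by period, counts by
#'   canonical motif class, and count_over_cutoff.
#' @export
summarize_ssrs <- function(loci, total_bases, long_cutoff = 20L) {
  n <- nrow(loci)
  density <- if (n == 0) NA_real_ else
    round_half_up((total_bases / 1000) / n, 1)
  by_period <- table(factor(loci$period, levels = 1:6))
  classes <- if (n > 0) canonical_motif_class(loci$motif) else character()
  by_class <- sort(table(classes), decreasing = TRUE)
  list(total_count = n,
       total_bases_in_ssrs = sum(loci$length),
       corpus_bases = total_bases,
       density_kb_per_ssr = density,
       by_period = by_period,
       by_class = by_class,
       count_over_cutoff = sum(loci$length > long_cutoff))
}

#' SSR loci as GRanges (for GFF3 export)
#'
#' @param loci SSR table from [find_ssrs()].
#' @return GRanges with type "microsatellite" and motif/period/units
#'   attributes.
#' @export
ssrs_as_granges <- function(loci) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$read_id,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = "+")
  S4Vectors::mcols(gr)$type <- rep("microsatellite", nrow(loci))
  S4Vectors::mcols(gr)$motif <- loci$motif
  S4Vectors::mcols(gr)$period <- loci$period
  S4Vectors::mcols(gr)$units <- loci$unit_count
  gr
}
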