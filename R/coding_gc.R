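# GC content, coding/non-coding partitioning driven by translated-homology
# ("protein signature") intervals, and GO term tabulation from a provided
# read-to-term table.

#' GC content of sequences
#'
#' @param seqs character vector of nucleotide sequences.
#' @return percent (G+C) / (A+C+G+T) per sequence; N and other letters are
#'   excluded from the denominator.  NA for sequences with no A/C/G/T.
#' @export
gc_content <- function(seqs) {
  up <- toupper(seqs)
  gc <- nchar(gsub("[^GC]", "", up))
  acgt <- nchar(gsub("[^ACGT]", "", up))
  ifelse(acgt == 0, NA_real_, 100 * gc / acgt)
}

# pooled GC over a whole corpus (single percentage)
gc_content_total <- function(seqs) {
  up <- toupper(seqs)
  gc <- sum(nchar(gsub("[^GC]", "", up)))
  acgt <- sum(nchar(gsub("[^ACGT]", "", up)))
  if (acgt == 0) NA_real_ else 100 * gc / acgt
}

#' Partition reads into coding and non-coding fractions by GC
#'
#' Signature intervals (unions of passing translated-alignment spans) mark
#' the coding fraction; everything else is non-coding.  GC percentages are
#' computed over non-N bases in each fraction.
#'
#' @param reads named character vector.
#' @param signatures data.frame with read_id, start, end (1-based
#'   inclusive, on the read).
#' @return list with overall_gc, coding_gc, noncoding_gc, coding_bases,
#'   noncoding_bases, signature_fraction (percent of reads with at least
#'   one signature interval).
#' @export
partition_gc <- function(reads, signatures) {
  if (is.null(names(reads))) stop("reads must be named")
  coding_parts <- character()
  noncoding_parts <- character()
  with_sig <- 0L
  for (id in names(reads)) {
    s <- toupper(reads[[id]])
    n <- nchar(s)
    sig <- signatures[signatures$read_id == id, , drop = FALSE]
    if (nrow(sig) == 0) {
      noncoding_parts <- c(noncoding_parts, s)
      next
    }
    if (any(sig$start < 1 | sig$end > n))
      stop("signature interval outside read bounds for ", id)
    with_sig <- with_sig + 1L
    red <- IRanges::reduce(IRanges::IRanges(sig$start, sig$end))
    cod <- substring(s, IRanges::start(red), IRanges::end(red))
    coding_parts <- c(coding_parts, cod)
    gaps <- IRanges::gaps(red, start = 1L, end = n)
    if (length(gaps) > 0)
      noncoding_parts <- c(noncoding_parts,
                           substring(s, IRanges::start(gaps),
                                     IRanges::end(gaps)))
  }
  list(overall_gc = gc_content_total(reads),
       coding_gc = gc_content_total(coding_parts),
       noncoding_gc = gc_content_total(noncoding_parts),
       coding_bases = sum(nchar(coding_parts)),
       noncoding_bases = sum(nchar(noncoding_parts)),
       signature_fraction = 100 * with_sig / length(reads))
}

#' Overall GC implied by a coding/non-coding partition
#'
#' Length-weighted mean of the two fraction GC percentages; used to check
#' the mutual consistency of reported GC triples.
#'
#' @param coding_gc,noncoding_gc percent GC of each fraction.
#' @param coding_bases,noncoding_bases fraction sizes (bases).
#' @return overall percent GC.
#' @export
gc_weighted_overall <- function(coding_gc, coding_bases, noncoding_gc,
                                noncoding_bases) {
  (coding_gc * coding_bases + noncoding_gc * noncoding_bases) /
    (coding_bases + noncoding_bases)
}

#' Tabulate GO annotations per namespace
#'
#' @param table data.frame with read_id, term_id, namespace.
#' @param namespaces allowed namespace labels.
#' @return list with per-term read counts and percentages within each
#'   namespace, reads-per-namespace counts, and totals (distinct annotated
#'   reads and distinct terms).
#' @export
tabulate_go <- function(table,
                        namespaces = c("molecular_function",
                                       "biological_process",
                                       "cellular_component")) {
  if (nrow(table) == 0)
    return(list(per_term = data.frame(namespace = character(),
                                      term_id = character(),
                                      reads = integer(), pct = numeric()),
                reads_per_namespace = setNames(integer(length(namespaces)),
                                               namespaces),
                total_reads = 0L, total_terms = 0L))
  unknown <- setdiff(unique(table$namespace), namespaces)
  if (length(unknown) > 0)
    stop("unknown namespace(s): ", paste(unknown, collapse = ", "))
  per_term <- do.call(rbind, lapply(split(table, table$namespace),
                                    function(tb) {
    counts <- vapply(split(tb$read_id, tb$term_id),
                     function(x) length(unique(x)), integer(1))
    ns_reads <- length(unique(tb$read_id))
    data.frame(namespace = tb$namespace[1], term_id = names(counts),
               reads = as.integer(counts),
               pct = round_half_up(100 * counts / ns_reads, 2),
               stringsAsFactors = FALSE)
  }))
  rownames(per_term) <- NULL
  ns_reads <- vapply(namespaces, function(ns) {
    length(unique(table$read_id[table$namespace == ns]))
  }, integer(1))
  list(per_term = per_term[order(per_term$namespace, -per_term$reads), ],
       reads_per_namespace = ns_reads,
       total_reads = length(unique(table$read_id)),
       total_terms = length(unique(table$term_id)))
}
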