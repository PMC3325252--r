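# Library coverage statistics.  The central identity is the Clarke-Carbon
# relation N = ln(1-P) / ln(1 - I/GS), linking the number of clones N with
# insert size I to the probability P that a given single-copy locus is
# present in a library of genome size GS.

# round half-up at `decimals`, the convention used for reported percentages
round_half_up <- function(x, decimals = 2) {
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Contamination rate from a hybridization screen
#'
#' @param positives clones giving a hybridization signal.
#' @param clones_screened clones screened.
#' @param decimals decimals for the reported percentage (half-up rounding).
#' @return percent of screened clones that are positive.
#' @export
contamination_rate <- function(positives, clones_screened, decimals = 2) {
  if (any(clones_screened <= 0)) stop("clones_screened must be positive")
  if (any(positives < 0 | positives > clones_screened))
    stop("positives must lie in [0, clones_screened]")
  round_half_up(100 * positives / clones_screened, decimals)
}

#' Haploid genome equivalents represented by a library
#'
#' Effective clones (after removing empty and organellar clones) times mean
#' insert size, divided by the haploid genome size.
#'
#' @param clone_count total clones in the library.
#' @param mean_insert mean insert size (bases).
#' @param empty_fraction proportion of empty clones.
#' @param organellar_fraction proportion of organellar-contaminant clones.
#' @param genome_size haploid genome size (bases).
#' @return genome equivalents (exact; round for reporting).
#' @export
genome_equivalents <- function(clone_count, mean_insert,
                               empty_fraction = 0,
                               organellar_fraction = 0,
                               genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive")
  if (any(clone_count < 0)) stop("clone_count must be non-negative")
  if (any(empty_fraction < 0 | organellar_fraction < 0))
    stop("fractions must be non-negative")
  if (any(empty_fraction + organellar_fraction >= 1))
    stop("empty_fraction + organellar_fraction must be < 1")
  clone_count * (1 - empty_fraction - organellar_fraction) *
    mean_insert / genome_size
}

#' Probability that a given locus is present in one or more libraries
#'
#' Inverts the Clarke-Carbon relation: P = 1 - (1 - I/GS)^N.  With vectors
#' of clone counts and insert sizes the libraries are combined, i.e. the
#' miss probabilities multiply.
#'
#' @param clones clones per library (vector for combined libraries).
#' @param insert mean insert size per library (bases).
#' @param genome_size haploid genome size (bases).
#' @return probability in [0, 1].
#' @export
p_find <- function(clones, insert, genome_size) {
  if (any(insert <= 0) || any(insert >= genome_size))
    stop("insert sizes must satisfy 0 < I < genome size")
  if (any(clones < 0)) stop("clone counts must be non-negative")
  log_miss <- sum(clones * log1p(-insert / genome_size))
  -expm1(log_miss)
}

#' Clones needed to reach a target coverage probability
#'
#' Smallest integer N with \code{p_find(N, insert, genome_size) >= P}.
#'
#' @param P target probability, in (0, 1).
#' @param insert mean insert size (bases).
#' @param genome_size haploid genome size (bases).
#' @return clone count (integer).
#' @export
clarke_carbon_clones <- function(P, insert, genome_size) {
  if (P <= 0 || P >= 1) stop("P must lie strictly between 0 and 1")
  if (insert <= 0 || insert >= genome_size)
    stop("insert must satisfy 0 < I < genome size")
  n <- log1p(-P) / log1p(-insert / genome_size)
  n_int <- ceiling(n - 1e-9)
  max(n_int, 1)
}

#' Insert size from a restriction digest
#'
#' One fragment must match the vector band (within \code{tol}); the insert
#' is the sum of the remaining fragments.
#'
#' @param fragment_sizes fragment sizes from the digest (kb).
#' @param vector_size expected vector band (kb).
#' @param tol match tolerance for the vector band (kb).
#' @return insert size (kb).
#' @export
insert_size_from_digest <- function(fragment_sizes, vector_size = 7.8,
                                    tol = 0.5) {
  d <- abs(fragment_sizes - vector_size)
  if (!any(d <= tol))
    stop("no fragment matches the vector band (", vector_size, " kb +/- ",
         tol, " kb)")
  vec_idx <- which.min(d)
  sum(fragment_sizes[-vec_idx])
}

#' Histogram of insert sizes
#'
#' @param inserts insert sizes (kb).
#' @param bin_width bin width (kb); bins are left-closed.
#' @return data.frame with bin_start, bin_end, count.
#' @export
insert_histogram <- function(inserts, bin_width = 10) {
  if (length(inserts) == 0)
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      count = integer()))
  lo <- floor(min(inserts) / bin_width) * bin_width
  hi <- ceiling((max(inserts) + 1e-9) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- findInterval(inserts, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             count = counts)
}

#' Library coverage report
#'
#' @param clone_count,mean_insert,empty_fraction,organellar_fraction,genome_size
#'   per-library values (vectors are combined for the joint probability).
#' @return list with per-library genome equivalents (exact and rounded),
#'   effective clone counts, and the combined probability of finding a
#'   given locus.
#' @export
coverage_report <- function(clone_count, mean_insert, empty_fraction = 0,
                            organellar_fraction = 0, genome_size) {
  eq <- genome_equivalents(clone_count, mean_insert, empty_fraction,
                           organellar_fraction, genome_size)
  eff <- clone_count * (1 - empty_fraction - organellar_fraction)
  list(genome_equivalents = eq,
       genome_equivalents_rounded = round_half_up(eq, 0),
       effective_clones = eff,
       p_find = p_find(eff, mean_insert, genome_size))
}
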