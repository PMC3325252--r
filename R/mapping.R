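# Comparative paired-end placement: hit filtering (identity / E-value /
# read coverage), deterministic best placement, pairing under an insert
# constraint, mate rescue inside a genomic window, coding-overlap
# fractions, and collinearity block detection on ortholog pair lists.

#' Filter alignment hits by the placement criteria
#'
#' Keeps hits with identity >= \code{min_identity}, E-value strictly below
#' \code{max_evalue} and read coverage strictly above \code{min_coverage}.
#' Coverage is aligned read bases over the full read length (masked bases
#' included in the denominator).
#'
#' @param hits tabular hit data.frame (see [read_hits()]).
#' @param read_lengths named vector of full read lengths.
#' @param min_identity percent identity bound.
#' @param max_evalue E-value bound (strict).
#' @param min_coverage read-coverage bound (strict), as a proportion.
#' @return the passing hits, with a coverage column added.
#' @export
filter_hits <- function(hits, read_lengths, min_identity = 75,
                        max_evalue = 1e-20, min_coverage = 0.5) {
  if (nrow(hits) == 0) {
    hits$coverage <- numeric()
    return(hits)
  }
  len <- read_lengths[hits$query_id]
  if (anyNA(len))
    stop("hits reference unknown read(s): ",
         paste(unique(hits$query_id[is.na(len)]), collapse = ", "))
  hits$coverage <- (abs(hits$q_end - hits$q_start) + 1) / len
  hits[hits$pct_identity >= min_identity & hits$evalue < max_evalue &
         hits$coverage > min_coverage, , drop = FALSE]
}

#' Deterministic best placement per read
#'
#' Highest bit score wins; ties break by lower E-value, then
#' lexicographically smaller subject id, then leftmost subject coordinate.
#'
#' @param hits passing hits from [filter_hits()].
#' @return one row per query_id.
#' @export
best_placement <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  s_left <- pmin(hits$s_start, hits$s_end)
  ord <- order(hits$query_id, -hits$bit_score, hits$evalue,
               hits$subject_id, s_left, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Pair placed reads by clone under an insert-size constraint
#'
#' Clones whose two ends are best-placed on the same reference sequence
#' with an outermost span of at most \code{max_insert} become paired
#' placements (microsyntenous regions); every other placed read is a
#' high-scoring singlet.
#'
#' @param placements best placements from [best_placement()].
#' @param pairs clone pair table from [pair_bes()] (\code{$pairs}).
#' @param max_insert maximum outermost span (bases).
#' @param strict_orientation additionally require convergent (inward
#'   facing) end orientations; off by default, matching the span-only rule.
#' @return list with \code{pairs} (clone_id, subject_id, span, start, end)
#'   and \code{singlets} (read ids), plus a category per placed read.
#' @export
call_pairs <- function(placements, pairs, max_insert = 5e5,
                       strict_orientation = FALSE) {
  placed <- placements$query_id
  out_pairs <- list()
  paired_reads <- character()
  if (nrow(pairs) > 0) for (i in seq_len(nrow(pairs))) {
    f <- pairs$forward_id[i]; r <- pairs$reverse_id[i]
    if (!(f %in% placed && r %in% placed)) next
    pf <- placements[placements$query_id == f, ][1, ]
    pr <- placements[placements$query_id == r, ][1, ]
    if (pf$subject_id != pr$subject_id) next
    lo <- min(pf$s_start, pf$s_end, pr$s_start, pr$s_end)
    hi <- max(pf$s_start, pf$s_end, pr$s_start, pr$s_end)
    span <- hi - lo + 1
    if (span > max_insert) next
    if (strict_orientation) {
      sf <- if (pf$s_start <= pf$s_end) "+" else "-"
      sr <- if (pr$s_start <= pr$s_end) "+" else "-"
      if (sf == sr) next                      # must face each other
      left_fwd <- min(pf$s_start, pf$s_end) <= min(pr$s_start, pr$s_end)
      leading <- if (left_fwd) sf else sr
      if (leading != "+") next
    }
    paired_reads <- c(paired_reads, f, r)
    out_pairs[[length(out_pairs) + 1L]] <-
      data.frame(clone_id = pairs$clone_id[i], subject_id = pf$subject_id,
                 start = lo, end = hi, span = span,
                 stringsAsFactors = FALSE)
  }
  pair_df <- if (length(out_pairs)) do.call(rbind, out_pairs) else
    data.frame(clone_id = character(), subject_id = character(),
               start = numeric(), end = numeric(), span = numeric(),
               stringsAsFactors = FALSE)
  singlets <- setdiff(placed, paired_reads)
  category <- setNames(ifelse(placed %in% paired_reads, "paired",
                              "high_scoring_singlet"), placed)
  list(pairs = pair_df, singlets = singlets, category = category)
}

#' Rescue an unplaced mate inside a genomic window
#'
#' When one end of a clone is placed (in coding sequence), its mate is
#' aligned by nucleotide local alignment against the reference window
#' within \code{max_insert} of the placement; a best hit passing the
#' identity and coverage bounds (no E-value constraint inside the window)
#' places the mate so the clone can re-enter [call_pairs()].
#'
#' @param mate_seq the unplaced mate's sequence.
#' @param mate_id its read id.
#' @param anchor one placement row (the placed end).
#' @param reference named character vector holding the reference sequence
#'   the anchor is placed on.
#' @param max_insert window half-width (bases).
#' @param min_identity,min_coverage acceptance bounds.
#' @param scheme a [scoring_scheme()].
#' @return a placement row for the mate, or NULL when no acceptable hit.
#' @export
rescue_mate <- function(mate_seq, mate_id, anchor, reference,
                        max_insert = 5e5, min_identity = 75,
                        min_coverage = 0.5, scheme = scoring_scheme()) {
  ref <- reference[[anchor$subject_id]]
  if (is.null(ref)) stop("reference sequence not found: ",
                         anchor$subject_id)
  a_lo <- min(anchor$s_start, anchor$s_end)
  a_hi <- max(anchor$s_start, anchor$s_end)
  w0 <- max(1, a_lo - max_insert)
  w1 <- min(nchar(ref), a_hi + max_insert)
  win <- substr(ref, w0, w1)
  hits <- local_align(toupper(mate_seq), win, scheme, query_id = mate_id,
                      subject_id = anchor$subject_id,
                      max_evalue = Inf,
                      seed_len = min(12L, nchar(mate_seq)))
  if (nrow(hits) == 0) return(NULL)
  hits$coverage <- (abs(hits$q_end - hits$q_start) + 1) / nchar(mate_seq)
  hits <- hits[hits$pct_identity >= min_identity &
                 hits$coverage > min_coverage, , drop = FALSE]
  if (nrow(hits) == 0) return(NULL)
  best <- hits[order(-hits$bit_score, hits$evalue), ][1, ]
  best$s_start <- best$s_start + w0 - 1
  best$s_end <- best$s_end + w0 - 1
  best
}

#' Fraction of placements overlapping coding features
#'
#' @param placements placement table with subject_id, s_start, s_end.
#' @param annotation a GRanges of gene/CDS features (or a GFF3 path).
#' @param feature_types feature types counted as coding.
#' @return percentage of placements overlapping a coding feature (2 dp).
#' @export
coding_overlap <- function(placements, annotation,
                           feature_types = c("CDS", "gene", "mRNA")) {
  if (is.character(annotation)) annotation <- read_gff3(annotation)
  if (nrow(placements) == 0) return(NA_real_)
  ann <- annotation[S4Vectors::mcols(annotation)$type %in% feature_types]
  gr <- GenomicRanges::GRanges(
    seqnames = placements$subject_id,
    ranges = IRanges::IRanges(
      start = pmin(placements$s_start, placements$s_end),
      end = pmax(placements$s_start, placements$s_end)))
  ov <- GenomicRanges::countOverlaps(gr, ann, ignore.strand = TRUE)
  round_half_up(100 * sum(ov > 0) / nrow(placements), 2)
}

#' Collinearity blocks from ortholog position pairs
#'
#' Chains ortholog pairs monotone in both genomes: increasing runs are
#' same-orientation blocks, decreasing runs are inversions.  Up to
#' \code{max_gap} genes may be skipped between consecutive pairs on either
#' side.  Blocks are extracted greedily: the longest chain first (ties:
#' fewest skipped genes, then same orientation before inverted, then
#' leftmost), removing its pairs and repeating.  Unchained pairs are
#' reported as rearranged.
#'
#' @param pairs data.frame with columns pos_a, pos_b (gene indices in the
#'   two genomes) and optionally strand_a, strand_b.
#' @param max_gap maximum genes skipped between consecutive chained pairs.
#' @param min_block minimum pairs per reported block.
#' @return list with \code{blocks} (data.frame: block id, orientation, and
#'   member pair indices as a list column) and \code{rearranged} (row
#'   indices of unchained pairs).
#' @export
collinearity_blocks <- function(pairs, max_gap = 2L, min_block = 2L) {
  n <- nrow(pairs)
  if (n == 0) return(list(blocks = data.frame(block = integer(),
                                              orientation = character(),
                                              length = integer()),
                          members = list(), rearranged = integer()))
  if (anyDuplicated(pairs$pos_a) || anyDuplicated(pairs$pos_b))
    stop("duplicate gene positions in the ortholog pairs")
  avail <- rep(TRUE, n)
  blocks <- list(); members <- list()
  repeat {
    best <- best_chain(pairs, which(avail), max_gap)
    if (is.null(best) || length(best$chain) < min_block) break
    blocks[[length(blocks) + 1L]] <-
      data.frame(block = length(blocks) + 1L,
                 orientation = best$orientation,
                 length = length(best$chain))
    members[[length(members) + 1L]] <- best$chain
    avail[best$chain] <- FALSE
  }
  list(blocks = if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block = integer(), orientation = character(),
               length = integer()),
    members = members, rearranged = which(avail))
}

# longest monotone chain (DP over pairs sorted by pos_a) among `idx`
best_chain <- function(pairs, idx, max_gap) {
  if (length(idx) == 0) return(NULL)
  p <- pairs[idx, , drop = FALSE]
  ord <- order(p$pos_a)
  p <- p[ord, , drop = FALSE]
  orig <- idx[ord]
  m <- nrow(p)
  best <- NULL
  for (dir in c("same", "inverted")) {
    len <- rep(1L, m); skip <- rep(0L, m); prev <- rep(0L, m)
    for (i in seq_len(m)) {
      for (j in seq_len(i - 1L)) {
        ga <- p$pos_a[i] - p$pos_a[j] - 1L
        gb <- if (dir == "same") p$pos_b[i] - p$pos_b[j] - 1L else
          p$pos_b[j] - p$pos_b[i] - 1L
        if (ga < 0 || ga > max_gap || gb < 0 || gb > max_gap) next
        cand_len <- len[j] + 1L
        cand_skip <- skip[j] + ga + gb
        if (cand_len > len[i] ||
            (cand_len == len[i] && cand_skip < skip[i])) {
          len[i] <- cand_len; skip[i] <- cand_skip; prev[i] <- j
        }
      }
    }
    top <- which(len == max(len))
    top <- top[which.min(skip[top])]
    chain <- integer()
    at <- top
    while (at != 0L) { chain <- c(at, chain); at <- prev[at] }
    cand <- list(chain = orig[chain], orientation = dir,
                 skip = skip[top])
    if (is.null(best) || length(cand$chain) > length(best$chain) ||
        (length(cand$chain) == length(best$chain) &&
         cand$skip < best$skip))
      best <- cand
  }
  best
}

#' Gene density
#'
#' @param count gene locus count.
#' @param corpus_bases bases of genomic sequence surveyed.
#' @return kb of sequence per gene (1 decimal); NA for a zero count.
#' @export
gene_density <- function(count, corpus_bases) {
  if (count == 0) return(NA_real_)
  round_half_up((corpus_bases / 1000) / count, 1)
}

#' Map reads onto a reference by seeded nucleotide alignment
#'
#' Convenience driver producing a tabular hit set: each read is seeded
#' against both strands of each reference sequence and the best diagonal
#' window is aligned exactly.
#'
#' @param reads named character vector of reads.
#' @param reference named character vector of reference sequences.
#' @param scheme a [scoring_scheme()].
#' @param seed_len seed length.
#' @param min_seeds minimum seeds before alignment is attempted.
#' @param max_evalue E-value cutoff.
#' @param window_pad subject window padding (bp).
#' @return tabular hit data.frame.
#' @export
map_reads_nt <- function(reads, reference, scheme = scoring_scheme(),
                         seed_len = 14L, min_seeds = 3L, max_evalue = 1e-10,
                         window_pad = 200L) {
  rows <- list()
  up_reads <- toupper(reads)
  for (ref_id in names(reference)) {
    ref <- toupper(reference[[ref_id]])
    rlen <- nchar(ref)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") ref else revcomp(ref)
      dm <- cpp_map_reads(subj, up_reads, seed_len)
      for (ri in which(dm[, "seeds"] >= min_seeds)) {
        q <- up_reads[[ri]]
        qlen <- nchar(q)
        diag <- dm[ri, "diag"]
        w0 <- max(0L, diag - window_pad)
        w1 <- min(rlen, diag + qlen + window_pad)
        if (w1 <= w0) next
        win <- substr(subj, w0 + 1L, w1)
        aln <- sw_nt(q, win, scheme)
        if (aln$score <= 0) next
        ev <- evalue_of(aln$score, qlen, rlen, scheme)
        if (ev > max_evalue) next
        rows[[length(rows) + 1L]] <-
          aln_row(aln, names(reads)[ri], ref_id, qlen, rlen, strand,
                  scheme, s_offset = w0, s_len_orig = rlen)
      }
    }
  }
  finalize_hits(rows, NA, NA)
}
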