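# Seeded local alignment with Karlin-Altschul style scores and E-values.
# Small problems run full affine-gap Smith-Waterman; for long subjects an
# exact k-mer seed selects the diagonal neighbourhood and the DP runs on
# that window only.  Additional hits on the same pair are recovered by
# masking the query span of each accepted hit and re-aligning.

#' Scoring scheme for local alignment
#'
#' Gap of length L scores \code{gap_open + L * gap_extend} (both negative;
#' \code{gap_open} is a one-off opening surcharge).  \code{lambda} and
#' \code{K} are the Karlin-Altschul constants used for bit scores and
#' E-values; the defaults are the standard ungapped blastn constants,
#' applied as an approximation.  Protein alignment uses the named
#' substitution matrix (looked up in Biostrings) with its own gap
#' penalties and constants.
#'
#' @param match,mismatch nucleotide match/mismatch scores.
#' @param gap_open,gap_extend gap penalties (negative).
#' @param lambda,K Karlin-Altschul constants for the nucleotide scores.
#' @param matrix substitution matrix name for translated mode.
#' @param aa_gap_open,aa_gap_extend,aa_lambda,aa_K protein-mode analogues.
#' @return list of class "scoring_scheme".
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = -5,
                           gap_extend = -2, lambda = 1.28, K = 0.46,
                           matrix = "BLOSUM62", aa_gap_open = -11,
                           aa_gap_extend = -1, aa_lambda = 0.267,
                           aa_K = 0.041) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 matrix = matrix, aa_gap_open = aa_gap_open,
                 aa_gap_extend = aa_gap_extend, aa_lambda = aa_lambda,
                 aa_K = aa_K),
            class = "scoring_scheme")
}

#' Bit score from a raw alignment score
#' @param score raw score.
#' @param scheme a [scoring_scheme()].
#' @param protein use the protein-mode constants.
#' @return bit score.
#' @export
bit_score <- function(score, scheme = scoring_scheme(), protein = FALSE) {
  lam <- if (protein) scheme$aa_lambda else scheme$lambda
  K <- if (protein) scheme$aa_K else scheme$K
  (lam * score - log(K)) / log(2)
}

#' E-value of a local alignment score
#' @param score raw score.
#' @param m,n effective query and subject lengths.
#' @param scheme a [scoring_scheme()].
#' @param protein use the protein-mode constants.
#' @return expected number of chance hits of at least this score.
#' @export
evalue_of <- function(score, m, n, scheme = scoring_scheme(),
                      protein = FALSE) {
  lam <- if (protein) scheme$aa_lambda else scheme$lambda
  K <- if (protein) scheme$aa_K else scheme$K
  K * m * n * exp(-lam * score)
}

# single best local alignment of two nucleotide strings (exact DP)
sw_nt <- function(a, b, scheme, traceback = TRUE) {
  cpp_align_nt(a, b, scheme$match, scheme$mismatch, scheme$gap_open,
               scheme$gap_extend, traceback)
}

# turn a C++ alignment result into one tabular hit row
aln_row <- function(aln, query_id, subject_id, qlen, slen, strand, scheme,
                    protein = FALSE, s_offset = 0L, s_len_orig = NULL) {
  s_start <- aln$s_start + s_offset
  s_end <- aln$s_end + s_offset
  if (strand == "-") {
    stopifnot(!is.null(s_len_orig))
    tmp <- s_start
    s_start <- s_len_orig - s_end + 1L
    s_end <- s_len_orig - tmp + 1L
    # tabular convention: minus-strand hits have s_start > s_end
    tmp <- s_start; s_start <- s_end; s_end <- tmp
  }
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = 100 * aln$n_match / max(aln$aln_len, 1),
             aln_len = aln$aln_len, mismatches = aln$n_mismatch,
             gap_opens = aln$n_gap_opens,
             q_start = aln$q_start, q_end = aln$q_end,
             s_start = s_start, s_end = s_end,
             evalue = evalue_of(aln$score, qlen, slen, scheme, protein),
             bit_score = bit_score(aln$score, scheme, protein),
             score = aln$score, strand = strand, status = aln$status,
             stringsAsFactors = FALSE)
}

#' Local alignment of two nucleotide sequences
#'
#' Searches both strands.  When the DP area is small the optimum is found
#' exactly; for long subjects an exact k-mer seed picks the most promising
#' diagonal and the DP is restricted to a window around it.  Further hits
#' between the same pair (e.g. an element fragmented by an insertion) are
#' found by masking the accepted query span and re-aligning.
#'
#' @param query,subject nucleotide strings (single sequences).
#' @param scheme a [scoring_scheme()].
#' @param query_id,subject_id ids used in the output table.
#' @param seed_len seed length for the heuristic path.
#' @param max_evalue discard hits above this E-value.
#' @param max_hits maximum hits reported per strand.
#' @param exact_area run exact full DP when qlen * slen is below this.
#' @param both_strands search the minus strand of the subject as well.
#' @param window_pad extra subject bases kept either side of the seeded
#'   diagonal window.
#' @return data.frame of hits (12 tabular columns plus score, strand,
#'   status).
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        query_id = "query", subject_id = "subject",
                        seed_len = 12L, max_evalue = 10,
                        max_hits = 8L, exact_area = 4e6,
                        both_strands = TRUE, window_pad = 200L) {
  qlen <- nchar(query); slen <- nchar(subject)
  if (qlen == 0 || slen == 0) stop("sequences must be non-empty")
  if (seed_len > min(qlen, slen))
    stop("seed_len exceeds the shorter sequence length")
  query <- toupper(query); subject <- toupper(subject)
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (strand in strands) {
    subj <- if (strand == "+") subject else revcomp(subject)
    if (as.double(qlen) * slen <= exact_area) {
      rows[[strand]] <- align_iterate(query, subj, scheme, query_id,
                                      subject_id, qlen, slen, strand,
                                      max_evalue, max_hits, 0L)
    } else {
      dm <- cpp_map_reads(subj, query, seed_len)
      if (dm[1, "seeds"] == 0) next
      diag <- dm[1, "diag"]
      w0 <- max(0L, diag - window_pad)
      w1 <- min(slen, diag + qlen + window_pad)
      if (w1 <= w0) next
      win <- substr(subj, w0 + 1L, w1)
      rows[[strand]] <- align_iterate(query, win, scheme, query_id,
                                      subject_id, qlen, slen, strand,
                                      max_evalue, max_hits, w0)
    }
  }
  finalize_hits(rows, qlen, slen)
}

# iterated best-hit extraction with query-span masking
align_iterate <- function(query, subj, scheme, query_id, subject_id,
                          qlen, slen, strand, max_evalue, max_hits,
                          s_offset) {
  out <- list()
  work <- query
  for (it in seq_len(max_hits)) {
    aln <- sw_nt(work, subj, scheme)
    if (aln$score <= 0) break
    ev <- evalue_of(aln$score, qlen, slen, scheme)
    if (ev <= max_evalue)
      out[[length(out) + 1L]] <-
        aln_row(aln, query_id, subject_id, qlen, slen, strand, scheme,
                s_offset = s_offset, s_len_orig = slen)
    if (ev > max_evalue) break
    substr(work, aln$q_start, aln$q_end) <-
      strrep("N", aln$q_end - aln$q_start + 1L)
  }
  out
}

finalize_hits <- function(rows, qlen = NA, slen = NA) {
  if (length(rows) && !is.data.frame(rows[[1]]))
    rows <- unlist(rows, recursive = FALSE)
  if (length(rows) == 0) {
    df <- empty_hits()
    df$score <- numeric(); df$strand <- character(); df$status <- character()
    return(df)
  }
  df <- do.call(rbind, rows)
  df[order(-df$bit_score, df$evalue), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Translated (six-frame) alignment against peptides
# ---------------------------------------------------------------------------

# standard-code translation of an ACGTN string; fuzzy codons become X
translate_nt <- function(seq) {
  n <- nchar(seq)
  if (n < 3) return("")
  n_aa <- n %/% 3
  codons <- substring(seq, 3 * seq_len(n_aa) - 2, 3 * seq_len(n_aa))
  code <- Biostrings::GENETIC_CODE
  aa <- code[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

blosum_matrix <- function(name = "BLOSUM62") {
  env <- new.env()
  data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Translated local alignment of a nucleotide query against a peptide
#'
#' All six frames are translated with the standard code; internal stops
#' split a frame into segments which are aligned independently, so stops
#' are never part of an alignment.  Hit coordinates are reported in
#' nucleotide space of the query, with the frame recorded (+1..+3 forward,
#' -1..-3 on the reverse complement).
#'
#' @param query nucleotide string (length >= 3).
#' @param peptide amino-acid string.
#' @param scheme a [scoring_scheme()]; its \code{matrix} names the
#'   substitution matrix.
#' @param query_id,subject_id ids for the output table.
#' @param max_evalue discard hits above this E-value.
#' @param min_segment_aa skip translated segments shorter than this.
#' @return data.frame of hits with nucleotide query coordinates, peptide
#'   subject coordinates and a \code{frame} column.
#' @export
translated_align <- function(query, peptide, scheme = scoring_scheme(),
                             query_id = "query", subject_id = "subject",
                             max_evalue = 10, min_segment_aa = 8L) {
  if (nchar(query) < 3) stop("query must be at least 3 nt")
  query <- toupper(query); peptide <- toupper(peptide)
  qlen <- nchar(query)
  sub <- blosum_matrix(scheme$matrix)
  alpha <- rownames(sub)
  code_of <- function(aa) {
    idx <- match(strsplit(aa, "")[[1]], alpha)
    idx[is.na(idx)] <- match("X", alpha)
    idx - 1L
  }
  pep_codes <- code_of(peptide)
  rows <- list()
  for (fr in 1:6) {
    rc <- fr > 3
    off <- (fr - 1L) %% 3L
    src <- if (rc) revcomp(query) else query
    aa <- translate_nt(substr(src, off + 1L, qlen))
    if (nchar(aa) == 0) next
    # split at stop codons; track 0-based aa offset of each segment
    segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
    seg_off <- 0L
    for (sg in segs) {
      sl <- nchar(sg)
      if (sl >= min_segment_aa) {
        aln <- cpp_align_coded(code_of(sg), pep_codes, sub,
                               scheme$aa_gap_open, scheme$aa_gap_extend)
        if (aln$score > 0) {
          ev <- evalue_of(aln$score, nchar(aa), nchar(peptide), scheme,
                          protein = TRUE)
          if (ev <= max_evalue) {
            g_start <- seg_off + aln$q_start  # 1-based aa in frame
            g_end <- seg_off + aln$q_end
            nt_start <- off + 3L * (g_start - 1L) + 1L
            nt_end <- off + 3L * g_end
            if (rc) {
              tmp <- nt_start
              nt_start <- qlen - nt_end + 1L
              nt_end <- qlen - tmp + 1L
            }
            row <- data.frame(
              query_id = query_id, subject_id = subject_id,
              pct_identity = 100 * aln$n_match / max(aln$aln_len, 1),
              aln_len = aln$aln_len, mismatches = aln$n_mismatch,
              gap_opens = aln$n_gap_opens,
              q_start = nt_start, q_end = nt_end,
              s_start = aln$s_start, s_end = aln$s_end,
              evalue = ev,
              bit_score = bit_score(aln$score, scheme, protein = TRUE),
              score = aln$score,
              frame = if (rc) -(off + 1L) else (off + 1L),
              stringsAsFactors = FALSE)
            rows[[length(rows) + 1L]] <- row
          }
        }
      }
      seg_off <- seg_off + sl + 1L  # + 1 for the stop
    }
  }
  if (length(rows) == 0) {
    df <- empty_hits()
    df$score <- numeric(); df$frame <- integer()
    return(df)
  }
  df <- do.call(rbind, rows)
  df[order(-df$bit_score, df$evalue), , drop = FALSE]
}
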