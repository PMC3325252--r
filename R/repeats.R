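# Homology-based annotation of known repeat elements against a class-labeled
# repeat library (RepeatMasker-style "name#class/subclass" FASTA headers),
# fragment merging, masking, low-complexity detection, and Table-style
# summarization.

#' Read a repeat library FASTA
#'
#' Headers follow the RepeatMasker dialect \code{name#class/subclass}; a
#' header without \code{#} gets class "Unclassified".
#'
#' @param path FASTA path.
#' @return data.frame with name, class_path, sequence.
#' @export
read_repeat_library <- function(path) {
  seqs <- read_fasta(path)
  parse_repeat_headers(seqs)
}

parse_repeat_headers <- function(seqs) {
  ids <- names(seqs)
  has <- grepl("#", ids, fixed = TRUE)
  data.frame(name = sub("#.*$", "", ids),
             class_path = ifelse(has, sub("^[^#]*#", "", ids),
                                 "Unclassified"),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Annotate reads with known repeat elements
#'
#' Seeded local alignment of every read against both strands of every
#' library entry.  Hits to the same element on the same read, in consistent
#' order and orientation and separated by no more than the merge gaps on
#' both read and element, are merged into one element (\code{merged_from}
#' counts the fragments), reflecting that elements fragmented by
#' insertions/deletions represent a single insertion event.
#'
#' @param reads named character vector of reads.
#' @param library repeat library data.frame from [read_repeat_library()].
#' @param scheme a [scoring_scheme()].
#' @param min_identity minimum percent identity per fragment.
#' @param min_length minimum fragment alignment length (bp).
#' @param max_evalue E-value cutoff per fragment.
#' @param merge_gap_read,merge_gap_element maximum gap (bp) between
#'   fragments on the read and on the element for merging.
#' @param seed_len seed length for the candidate-pair prefilter.
#' @param min_seeds minimum shared seeds for a read/element pair to be
#'   aligned at all.
#' @param mask "soft" (lowercase), "hard" (N), or "none".
#' @return list with \code{hits} (one row per merged element: read_id,
#'   name, class_path, read_start, read_end, elem_start, elem_end, strand,
#'   pct_identity, merged_from) and \code{masked} reads.
#' @export
annotate_repeats <- function(reads, library, scheme = scoring_scheme(),
                             min_identity = 70, min_length = 50,
                             max_evalue = 1e-5,
                             merge_gap_read = 100, merge_gap_element = 500,
                             seed_len = 12L, min_seeds = 2L,
                             mask = c("soft", "hard", "none")) {
  mask <- match.arg(mask)
  if (nrow(library) == 0) stop("repeat library is empty")
  if (is.null(names(reads))) stop("reads must be named")
  frag_rows <- list()
  for (e in seq_len(nrow(library))) {
    elem <- toupper(library$sequence[e])
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") elem else revcomp(elem)
      # candidate reads must share seeds with the element
      dm <- cpp_map_reads(subj, toupper(reads), seed_len)
      cand <- which(dm[, "seeds"] >= min_seeds)
      for (ri in cand) {
        hits <- align_iterate(toupper(reads[[ri]]), subj, scheme,
                              names(reads)[ri], library$name[e],
                              nchar(reads[[ri]]), nchar(elem), "+",
                              max_evalue, 6L, 0L)
        for (h in hits) {
          if (h$pct_identity < min_identity || h$aln_len < min_length) next
          es <- h$s_start; ee <- h$s_end
          if (strand == "-") {       # element coords back on its + strand
            es <- nchar(elem) - h$s_end + 1L
            ee <- nchar(elem) - h$s_start + 1L
          }
          frag_rows[[length(frag_rows) + 1L]] <- data.frame(
            read_id = h$query_id, name = library$name[e],
            class_path = library$class_path[e],
            read_start = h$q_start, read_end = h$q_end,
            elem_start = es, elem_end = ee, strand = strand,
            pct_identity = h$pct_identity, score = h$score,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  frags <- if (length(frag_rows)) do.call(rbind, frag_rows) else
    data.frame(read_id = character(), name = character(),
               class_path = character(), read_start = integer(),
               read_end = integer(), elem_start = integer(),
               elem_end = integer(), strand = character(),
               pct_identity = numeric(), score = numeric(),
               stringsAsFactors = FALSE)
  hits <- merge_repeat_fragments(frags, merge_gap_read, merge_gap_element)
  masked <- mask_reads(reads, hits, mask)
  list(hits = hits, masked = masked)
}

# chain fragments of one (read, element, strand) into merged elements
merge_repeat_fragments <- function(frags, gap_read, gap_elem) {
  if (nrow(frags) == 0) {
    frags$merged_from <- integer()
    return(frags)
  }
  key <- paste(frags$read_id, frags$name, frags$strand, sep = "\r")
  out <- lapply(split(seq_len(nrow(frags)), key), function(idx) {
    f <- frags[idx, , drop = FALSE]
    f <- f[order(f$read_start, f$elem_start), , drop = FALSE]
    groups <- integer(nrow(f)); groups[1] <- 1L
    g <- 1L
    if (nrow(f) > 1) for (i in 2:nrow(f)) {
      prev <- f[i - 1L, ]; cur <- f[i, ]
      gap_r <- cur$read_start - prev$read_end - 1L
      # order on the element must follow strand orientation
      if (cur$strand == "+") {
        gap_e <- cur$elem_start - prev$elem_end - 1L
        ok <- gap_e >= -10 && gap_e <= gap_elem
      } else {
        gap_e <- prev$elem_start - cur$elem_end - 1L
        ok <- gap_e >= -10 && gap_e <= gap_elem
      }
      ok <- ok && gap_r >= -10 && gap_r <= gap_read
      if (!ok) g <- g + 1L
      groups[i] <- g
    }
    do.call(rbind, lapply(split(seq_len(nrow(f)), groups), function(jj) {
      m <- f[jj, , drop = FALSE]
      data.frame(read_id = m$read_id[1], name = m$name[1],
                 class_path = m$class_path[1],
                 read_start = min(m$read_start), read_end = max(m$read_end),
                 elem_start = min(m$elem_start), elem_end = max(m$elem_end),
                 strand = m$strand[1],
                 pct_identity = {
                   w <- m$read_end - m$read_start + 1
                   sum(m$pct_identity * w) / sum(w)
                 },
                 merged_from = nrow(m), stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$read_id, res$read_start), , drop = FALSE]
}

#' Mask repeat hits in reads
#'
#' @param reads named character vector.
#' @param hits merged hit table (read_id, read_start, read_end).
#' @param mask "soft" lowercases hit spans, "hard" replaces them with N,
#'   "none" returns the reads untouched.
#' @return masked reads.
#' @export
mask_reads <- function(reads, hits, mask = c("soft", "hard", "none")) {
  mask <- match.arg(mask)
  if (mask == "none" || nrow(hits) == 0) return(reads)
  for (id in unique(hits$read_id)) {
    h <- hits[hits$read_id == id, , drop = FALSE]
    s <- reads[[id]]
    for (i in seq_len(nrow(h))) {
      seg <- substr(s, h$read_start[i], h$read_end[i])
      rep <- if (mask == "soft") tolower(seg) else
        strrep("N", nchar(seg))
      substr(s, h$read_start[i], h$read_end[i]) <- rep
    }
    reads[[id]] <- s
  }
  reads
}

#' Detect low-complexity intervals
#'
#' Sliding windows whose Shannon entropy over trinucleotides falls below a
#' threshold are flagged and merged.
#'
#' @param reads named character vector.
#' @param window,step window size and step (bp).
#' @param threshold entropy threshold (bits).
#' @return data.frame with read_id, start, end (1-based inclusive).
#' @export
detect_low_complexity <- function(reads, window = 64L, step = 32L,
                                  threshold = 1.4) {
  if (is.null(names(reads))) names(reads) <- as.character(seq_along(reads))
  out <- lapply(names(reads), function(id) {
    m <- cpp_low_complexity(toupper(reads[[id]]), window, step, threshold)
    if (nrow(m) == 0) return(NULL)
    red <- IRanges::reduce(IRanges::IRanges(start = m[, 1], end = m[, 2]))
    data.frame(read_id = id, start = IRanges::start(red),
               end = IRanges::end(red), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(read_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out
}

#' Summarize repeat hits per class
#'
#' Counts merged elements and bases per hierarchical class.  Bases are
#' computed on per-read interval unions within each class, so overlapping
#' fragments are never double counted; parent classes aggregate their
#' children (a parent's own hits plus all descendants).
#'
#' @param hits merged hit table from [annotate_repeats()].
#' @param corpus_bases total bases of the analysed corpus.
#' @param low_complexity optional interval table from
#'   [detect_low_complexity()], reported under class "LowComplexity".
#' @param interspersed_roots top-level classes counted as interspersed
#'   (transposon) repeats.
#' @return data.frame with class_path, element_count, bases, pct (2 dp),
#'   plus attribute "interspersed" holding the interspersed totals.
#' @export
summarize_repeats <- function(hits, corpus_bases, low_complexity = NULL,
                              interspersed_roots = c("Retroelements",
                                                     "DNATransposon",
                                                     "Unclassified")) {
  if (corpus_bases <= 0) stop("corpus_bases must be positive")
  rows <- hits[, c("read_id", "class_path", "read_start", "read_end"),
               drop = FALSE]
  if (!is.null(low_complexity) && nrow(low_complexity) > 0) {
    lc <- data.frame(read_id = low_complexity$read_id,
                     class_path = "LowComplexity",
                     read_start = low_complexity$start,
                     read_end = low_complexity$end,
                     stringsAsFactors = FALSE)
    rows <- rbind(rows, lc)
  }
  all_paths <- unique(rows$class_path)
  # every ancestor of an observed path is reported as well
  ancestors <- unique(unlist(lapply(strsplit(all_paths, "/"), function(p) {
    vapply(seq_along(p), function(k) paste(p[1:k], collapse = "/"),
           character(1))
  })))
  counts <- if (nrow(hits)) table(hits$class_path) else table(character())
  lc_count <- if (!is.null(low_complexity)) nrow(low_complexity) else 0L
  summ <- do.call(rbind, lapply(sort(ancestors), function(cp) {
    sel <- rows$class_path == cp |
      startsWith(rows$class_path, paste0(cp, "/"))
    sub <- rows[sel, , drop = FALSE]
    bases <- union_bases(sub)
    n_elem <- if (cp == "LowComplexity") lc_count else {
      own <- names(counts) == cp | startsWith(names(counts),
                                              paste0(cp, "/"))
      sum(counts[own])
    }
    data.frame(class_path = cp, element_count = as.integer(n_elem),
               bases = bases,
               pct = round_half_up(100 * bases / corpus_bases, 2),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summ))
    summ <- data.frame(class_path = character(), element_count = integer(),
                       bases = numeric(), pct = numeric(),
                       stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  inter_sel <- rows$class_path %in% interspersed_roots |
    grepl(paste0("^(", paste(interspersed_roots, collapse = "|"), ")/"),
          rows$class_path)
  inter_bases <- union_bases(rows[inter_sel, , drop = FALSE])
  attr(summ, "interspersed") <-
    list(bases = inter_bases,
         pct = round_half_up(100 * inter_bases / corpus_bases, 2))
  summ
}

# total bases covered by per-read unions of [read_start, read_end]
union_bases <- function(rows) {
  if (nrow(rows) == 0) return(0)
  sum(vapply(split(rows, rows$read_id), function(r) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = r$read_start, end = r$read_end))))
  }, numeric(1)))
}

#' Headline ratios from a repeat summary table
#'
#' Works on any table with hierarchical \code{class_path},
#' \code{element_count} and \code{bases} columns (e.g. a published repeat
#' census transcribed as input, or the output of [summarize_repeats()]).
#' A parent's value is its own row when present, otherwise the sum of its
#' descendants.
#'
#' @param summary data.frame with class_path, element_count, bases.
#' @param corpus_bases denominator for genome-fraction percentages.
#' @param decimals decimals for reported percentages.
#' @return list: class1_share_pct (retroelements as % of all transposons),
#'   class2_share_pct, ltr_share_pct (LTR elements as % of
#'   retroelements), retro_fraction_pct (retroelement bases as % of
#'   corpus), enspm_share_pct (En-Spm as % of DNA transposons),
#'   gypsy_copia_ratio.
#' @export
repeat_summary_ratios <- function(summary, corpus_bases, decimals = 2) {
  val <- function(cp, col) {
    own <- summary[[col]][summary$class_path == cp]
    if (length(own) == 1 && !is.na(own)) return(own)
    sel <- startsWith(summary$class_path, paste0(cp, "/"))
    # avoid double counting: only direct children (deeper rows are included
    # in their parents when parents exist)
    kids <- summary$class_path[sel]
    depth <- lengths(strsplit(kids, "/"))
    sum(summary[[col]][sel][depth == min(depth)])
  }
  c1 <- val("Retroelements", "element_count")
  c2 <- val("DNATransposon", "element_count")
  ltr <- val("Retroelements/LTR", "element_count")
  gypsy <- val("Retroelements/LTR/Ty3-Gypsy", "element_count")
  copia <- val("Retroelements/LTR/Ty1-Copia", "element_count")
  enspm <- val("DNATransposon/En-Spm", "element_count")
  retro_bases <- val("Retroelements", "bases")
  list(
    class1_share_pct = round_half_up(100 * c1 / (c1 + c2), decimals),
    class2_share_pct = round_half_up(100 * c2 / (c1 + c2), decimals),
    ltr_share_pct = round_half_up(100 * ltr / c1, decimals),
    retro_fraction_pct = round_half_up(100 * retro_bases / corpus_bases,
                                       decimals),
    enspm_share_pct = round_half_up(100 * enspm / c2, decimals),
    gypsy_copia_ratio = if (length(copia) && copia > 0) gypsy / copia
    else NA_real_)
}
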