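# De novo repeat-family discovery from masked BES: all-vs-all
# self-comparison, support thresholding, single-linkage clustering of the
# matching segments, medoid star alignment with majority consensus, known-
# database filtering, and genome copy-number extrapolation.

#' Self-comparison of masked reads
#'
#' A read pair counts as a match iff some local alignment between them
#' contains a stretch of at least \code{window} alignment columns at
#' \code{min_identity} percent identity or better and the alignment passes
#' the E-value cutoff.  Reads should have known repeats masked first; soft
#' masked (lowercase) bases are hard-masked internally so they can neither
#' seed nor match.
#'
#' @param reads named character vector of masked reads.
#' @param window minimum high-identity stretch (alignment columns).
#' @param min_identity minimum percent identity within the stretch.
#' @param max_evalue E-value cutoff for the supporting alignment.
#' @param scheme a [scoring_scheme()].
#' @param seed_len,min_shared k-mer prefilter: only read pairs sharing at
#'   least \code{min_shared} exact seeds are aligned.
#' @return list with \code{counts} (named integer: distinct partners per
#'   read) and \code{matches} (pair table with the matching segment
#'   coordinates on both reads).
#' @export
self_compare <- function(reads, window = 100L, min_identity = 90,
                         max_evalue = 1e-50, scheme = scoring_scheme(),
                         seed_len = 16L, min_shared = 4L) {
  if (window < seed_len) stop("window must be >= seed length")
  ids <- names(reads)
  if (is.null(ids)) stop("reads must be named")
  hard <- chartr("acgtn", "NNNNN", reads)
  cand <- cpp_shared_kmer_pairs(hard, seed_len, min_shared)
  # same-strand duplicates arise from opposite clone ends: search both
  # strands of the second read as well
  rows <- list()
  if (nrow(cand) > 0) for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    hit <- best_window_match(hard[[i]], hard[[j]], scheme, window,
                             min_identity, max_evalue)
    if (!is.null(hit))
      rows[[length(rows) + 1L]] <-
        data.frame(read_a = ids[i], read_b = ids[j],
                   a_start = hit$q_start, a_end = hit$q_end,
                   b_start = hit$s_start, b_end = hit$s_end,
                   strand = hit$strand, pct_identity = hit$pct_identity,
                   stringsAsFactors = FALSE)
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_a = character(), read_b = character(),
               a_start = integer(), a_end = integer(),
               b_start = integer(), b_end = integer(),
               strand = character(), pct_identity = numeric(),
               stringsAsFactors = FALSE)
  counts <- setNames(integer(length(ids)), ids)
  if (nrow(matches) > 0) {
    tab <- table(c(matches$read_a, matches$read_b))
    counts[names(tab)] <- as.integer(tab)
  }
  list(counts = counts, matches = matches)
}

# best alignment between two reads (plus strand only: clone ends sampled
# from opposite strands are handled by the caller's strand loop) that
# contains a >= window stretch at >= min_identity; NULL when none does
best_window_match <- function(a, b, scheme, window, min_identity,
                              max_evalue) {
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") b else revcomp(b)
    aln <- sw_nt(a, subj, scheme)
    if (aln$score <= 0) next
    ev <- evalue_of(aln$score, nchar(a), nchar(b), scheme)
    if (ev > max_evalue) next
    if (aln$aln_len < window) next
    if (!has_identity_window(aln$status, window, min_identity)) next
    s_start <- aln$s_start; s_end <- aln$s_end
    if (strand == "-") {
      s_start <- nchar(b) - aln$s_end + 1L
      s_end <- nchar(b) - aln$s_start + 1L
    }
    return(list(q_start = aln$q_start, q_end = aln$q_end,
                s_start = s_start, s_end = s_end, strand = strand,
                pct_identity = 100 * aln$n_match / aln$aln_len))
  }
  NULL
}

# does the alignment column string contain a `window`-column stretch with
# at least min_identity percent matches?
has_identity_window <- function(status, window, min_identity) {
  v <- as.integer(strsplit(status, "")[[1]] == "M")
  n <- length(v)
  if (n < window) return(FALSE)
  cs <- cumsum(v)
  best <- max(cs[window:n] - c(0, cs)[1:(n - window + 1)])
  100 * best / window >= min_identity
}

#' Select repetitive reads by match support
#'
#' @param profile result of [self_compare()] (or its \code{counts}).
#' @param min_support minimum number of distinct matching reads.
#' @return character vector of read ids with count >= min_support.
#' @export
select_repetitive <- function(profile, min_support = 6L) {
  counts <- if (is.list(profile)) profile$counts else profile
  names(counts)[counts >= min_support]
}

#' Build consensus repeat candidates from self-match segments
#'
#' Each selected read contributes its multi-witness segment cores: maximal
#' runs where at least two match intervals agree.  Requiring two witnesses
#' trims the flanks contributed by clones that merely overlap on the
#' genome and sharpens element boundaries.  Cores are clustered by single
#' linkage at \code{cluster_identity} percent over at least \code{min_len}
#' aligned bp, where the linking alignment must also cover most of the
#' shorter segment -- otherwise a segment that straddles two adjacent
#' elements would chimerize both families into one cluster.  Each cluster
#' is collapsed by a star alignment to its medoid (highest total
#' similarity; ties broken by the lexicographically smallest segment id)
#' with column-majority consensus; consensus positions covered by fewer
#' than half the members are trimmed.
#'
#' @param profile result of [self_compare()].
#' @param reads the masked reads that produced the profile.
#' @param selected read ids from [select_repetitive()]; defaults to
#'   applying \code{min_support} to the profile.
#' @param cluster_identity percent identity for single-linkage clustering.
#' @param min_len,max_len consensus length bounds (bp); candidates outside
#'   are discarded.
#' @param min_support minimum number of distinct supporting reads.
#' @param seg_max match segments longer than this are excluded from
#'   clustering: they arise from clones overlapping on the genome (whole
#'   shared regions align end to end), not from a dispersed element, and
#'   would chimerize unrelated families through single linkage.  Defaults
#'   to \code{max_len + 100}.
#' @param link_coverage fraction of the shorter segment the linking
#'   alignment must cover.
#' @param scheme a [scoring_scheme()].
#' @return data.frame with sre_id, consensus, length, support; the member
#'   segment table is attached as attribute "members".
#' @export
build_consensus <- function(profile, reads, selected = NULL,
                            cluster_identity = 80, min_len = 80L,
                            max_len = 300L, min_support = 6L,
                            seg_max = max_len + 100L, link_coverage = 0.8,
                            scheme = scoring_scheme()) {
  if (is.null(selected)) selected <- select_repetitive(profile, min_support)
  empty <- data.frame(sre_id = character(), consensus = character(),
                      length = integer(), support = integer(),
                      stringsAsFactors = FALSE)
  if (length(selected) == 0) return(empty)
  m <- profile$matches
  m <- m[(m$a_end - m$a_start + 1L) <= seg_max &
           (m$b_end - m$b_start + 1L) <= seg_max, , drop = FALSE]
  segs <- rbind(
    data.frame(read_id = m$read_a, start = m$a_start, end = m$a_end,
               stringsAsFactors = FALSE),
    data.frame(read_id = m$read_b, start = m$b_start, end = m$b_end,
               stringsAsFactors = FALSE))
  segs <- segs[segs$read_id %in% selected, , drop = FALSE]
  if (nrow(segs) == 0) return(empty)
  # per read: maximal runs supported by >= 2 match intervals (falling back
  # to the plain union when no position has two witnesses)
  seg_list <- do.call(rbind, lapply(split(segs, segs$read_id), function(s) {
    iv <- IRanges::IRanges(s$start, s$end)
    core <- IRanges::slice(IRanges::coverage(iv), lower = 2L,
                           rangesOnly = TRUE)
    if (length(core) == 0) core <- IRanges::reduce(iv)
    core <- core[IRanges::width(core) >= min_len]
    if (length(core) == 0) return(NULL)
    data.frame(read_id = s$read_id[1], start = IRanges::start(core),
               end = IRanges::end(core), stringsAsFactors = FALSE)
  }))
  if (is.null(seg_list) || nrow(seg_list) == 0) return(empty)
  rownames(seg_list) <- NULL
  seg_list$seg_id <- paste0(seg_list$read_id, ":", seg_list$start, "-",
                            seg_list$end)
  seg_list$sequence <- toupper(substr(reads[seg_list$read_id],
                                      seg_list$start, seg_list$end))
  n <- nrow(seg_list)
  # pairwise linkage under a k-mer prefilter
  cand <- cpp_shared_kmer_pairs(seg_list$sequence, 12L, 2L)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  sim <- matrix(0, n, n)
  if (nrow(cand) > 0) for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    aln <- best_of_strands(seg_list$sequence[i], seg_list$sequence[j],
                           scheme)
    shorter <- min(nchar(seg_list$sequence[i]),
                   nchar(seg_list$sequence[j]))
    if (aln$aln_len >= min_len &&
        aln$aln_len >= link_coverage * shorter &&
        100 * aln$n_match / aln$aln_len >= cluster_identity) {
      sim[i, j] <- sim[j, i] <- aln$score
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  members_out <- list()
  k <- 0L
  for (root in unique(roots)) {
    idx <- which(roots == root)
    support <- length(unique(seg_list$read_id[idx]))
    if (support < min_support) next
    medoid <- pick_medoid(idx, sim, seg_list$seg_id)
    cons <- star_consensus(seg_list$sequence[medoid],
                           seg_list$sequence[setdiff(idx, medoid)],
                           scheme)
    if (nchar(cons) < min_len || nchar(cons) > max_len) next
    k <- k + 1L
    id <- sprintf("SRE%04d", k)
    out[[k]] <- data.frame(sre_id = id, consensus = cons,
                           length = nchar(cons), support = support,
                           stringsAsFactors = FALSE)
    members_out[[k]] <- data.frame(sre_id = id,
                                   seg_id = seg_list$seg_id[idx],
                                   read_id = seg_list$read_id[idx],
                                   start = seg_list$start[idx],
                                   end = seg_list$end[idx],
                                   stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  attr(res, "members") <- if (length(members_out))
    do.call(rbind, members_out) else NULL
  res
}

best_of_strands <- function(a, b, scheme) {
  f <- sw_nt(a, b, scheme)
  r <- sw_nt(a, revcomp(b), scheme)
  if (r$score > f$score) r else f
}

pick_medoid <- function(idx, sim, seg_ids) {
  tot <- rowSums(sim[idx, idx, drop = FALSE])
  best <- which(tot == max(tot))
  # tie-break: lexicographically smallest segment id
  idx[best][order(seg_ids[idx[best]], method = "radix")][1]
}

# star alignment of members onto the medoid; per-column majority vote over
# positions covered by at least half of all members (medoid included)
star_consensus <- function(medoid, members, scheme) {
  L <- nchar(medoid)
  n_members <- length(members) + 1L
  votes <- matrix(0L, nrow = 5, ncol = L,
                  dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  med_chars <- strsplit(medoid, "")[[1]]
  occupancy <- rep(1L, L)
  for (p in seq_len(L)) {
    b <- med_chars[p]
    if (b %in% rownames(votes)) votes[b, p] <- votes[b, p] + 1L
  }
  for (mem in members) {
    f <- sw_nt(mem, medoid, scheme)
    r <- sw_nt(revcomp(mem), medoid, scheme)
    if (r$score > f$score) {
      aln <- r; mem_seq <- revcomp(mem)
    } else {
      aln <- f; mem_seq <- mem
    }
    if (aln$score <= 0) next
    cols <- strsplit(aln$status, "")[[1]]
    qi <- aln$q_start; si <- aln$s_start
    mem_chars <- strsplit(mem_seq, "")[[1]]
    for (cc in cols) {
      if (cc == "M" || cc == "X") {
        b <- mem_chars[qi]
        if (b %in% rownames(votes)) votes[b, si] <- votes[b, si] + 1L
        occupancy[si] <- occupancy[si] + 1L
        qi <- qi + 1L; si <- si + 1L
      } else if (cc == "I") {      # insertion relative to the medoid
        qi <- qi + 1L
      } else {                     # deletion: medoid column uncovered
        si <- si + 1L
      }
    }
  }
  keep <- occupancy >= n_members / 2
  if (!any(keep)) return("")
  cons <- apply(votes[1:4, keep, drop = FALSE], 2, function(v) {
    c("A", "C", "G", "T")[which.max(v)]
  })
  paste(cons, collapse = "")
}

#' Remove candidates matching known databases
#'
#' A candidate is removed when it has any nucleotide hit against a
#' nucleotide database or any translated hit against a peptide database at
#' E-value at or below the cutoff.
#'
#' @param candidates data.frame from [build_consensus()].
#' @param nt_databases list of named character vectors (nucleotide sets).
#' @param pep_databases list of named character vectors (peptide sets).
#' @param max_evalue removal cutoff.
#' @param scheme a [scoring_scheme()].
#' @return the retained candidates.
#' @export
filter_known <- function(candidates, nt_databases = list(),
                         pep_databases = list(), max_evalue = 1e-4,
                         scheme = scoring_scheme()) {
  if (nrow(candidates) == 0) return(candidates)
  known <- vapply(seq_len(nrow(candidates)), function(i) {
    q <- candidates$consensus[i]
    for (db in nt_databases) {
      for (s in db) {
        h <- local_align(q, s, scheme, max_evalue = max_evalue,
                         seed_len = min(12L, nchar(q), nchar(s)))
        if (nrow(h) > 0) return(TRUE)
      }
    }
    for (db in pep_databases) {
      for (s in db) {
        h <- translated_align(q, s, scheme, max_evalue = max_evalue)
        if (nrow(h) > 0) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  res <- candidates[!known, , drop = FALSE]
  mem <- attr(candidates, "members")
  if (!is.null(mem))
    attr(res, "members") <- mem[mem$sre_id %in% res$sre_id, , drop = FALSE]
  res
}

#' Extrapolate genome copy number from BES support
#'
#' @param support copies observed in the BES sample.
#' @param sampled_fraction fraction of the genome covered by the sample.
#' @return estimated genome copies, truncated to an integer.
#' @export
extrapolate_copies <- function(support, sampled_fraction) {
  if (any(sampled_fraction <= 0) || any(sampled_fraction > 1))
    stop("sampled_fraction must lie in (0, 1]")
  floor(support / sampled_fraction)
}

#' Mine novel repeat families from masked reads
#'
#' Runs [self_compare()], [select_repetitive()], [build_consensus()] and
#' [filter_known()], then extrapolates genome copy numbers from the
#' sampled genome fraction.
#'
#' @param reads masked reads (named character vector).
#' @param genome_size genome size (bases) for the sampled fraction.
#' @param min_support support threshold.
#' @param window,min_identity,max_evalue self-comparison parameters.
#' @param nt_databases,pep_databases known databases for [filter_known()].
#' @param scheme a [scoring_scheme()].
#' @param ... passed to [build_consensus()].
#' @return list with profile, candidates, catalog (retained candidates
#'   with genome_copies_est) and sampled_fraction.
#' @export
mine_sres <- function(reads, genome_size, min_support = 6L, window = 100L,
                      min_identity = 90, max_evalue = 1e-50,
                      nt_databases = list(), pep_databases = list(),
                      scheme = scoring_scheme(), ...) {
  profile <- self_compare(reads, window, min_identity, max_evalue, scheme)
  cands <- build_consensus(profile, reads, min_support = min_support,
                           scheme = scheme, ...)
  kept <- filter_known(cands, nt_databases, pep_databases, scheme = scheme)
  sampled <- min(1, sum(nchar(reads)) / genome_size)
  if (nrow(kept) > 0)
    kept$genome_copies_est <- extrapolate_copies(kept$support, sampled)
  else kept$genome_copies_est <- integer()
  list(profile = profile, candidates = cands, catalog = kept,
       sampled_fraction = sampled)
}
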