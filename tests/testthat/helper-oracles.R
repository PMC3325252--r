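# Independent oracles and small data builders used across the suite.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force SSR scanner: enumerates every maximal perfect run of every
# period 1..6 via pairwise position comparison, applies the length/unit
# thresholds, keeps primitive motifs, and reports identical intervals once
# under their smallest period.
brute_ssrs <- function(seq, min_len_short = 12L, min_units_long = 4L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  acgt <- ch %in% c("A", "C", "G", "T")
  rows <- list()
  for (p in 1:6) {
    if (n <= p) next
    eq <- ch[1:(n - p)] == ch[(1 + p):n] & acgt[1:(n - p)]
    r <- rle(eq)
    pos <- 1L
    for (k in seq_along(r$lengths)) {
      if (r$values[k]) {
        start <- pos
        len <- r$lengths[k] + p
        pass <- if (p <= 3) len >= min_len_short else
          len >= min_units_long * p
        if (pass) {
          motif <- paste(ch[start:(start + p - 1L)], collapse = "")
          primitive <- TRUE
          for (d in seq_len(p - 1L)) {
            if (p %% d == 0 &&
                motif == strrep(substr(motif, 1, d), p / d)) {
              primitive <- FALSE
              break
            }
          }
          if (primitive)
            rows[[length(rows) + 1L]] <-
              data.frame(start = start, end = start + len - 1L,
                         period = p, motif = motif)
        }
      }
      pos <- pos + r$lengths[k]
    }
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(), end = integer(),
                      period = integer(), motif = character()))
  df <- do.call(rbind, rows)
  # identical intervals: keep smallest period
  df <- df[order(df$start, df$end, df$period), ]
  dup <- duplicated(df[, c("start", "end")])
  df <- df[!dup, ]
  df[order(df$start, df$period), ]
}

# exhaustive longest monotone chain (either direction) with a per-side gap
# bound, over all subsets -- for small ortholog lists only
brute_longest_chain <- function(pairs, max_gap = 2L) {
  n <- nrow(pairs)
  if (n == 0) return(0L)
  ord <- order(pairs$pos_a)
  pa <- pairs$pos_a[ord]; pb <- pairs$pos_b[ord]
  best <- 1L
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(idx) <= best) next
    a <- pa[idx]; b <- pb[idx]
    ga <- diff(a) - 1L
    gb <- diff(b) - 1L
    inc <- all(gb >= 0L & gb <= max_gap)
    dec <- all(-gb - 2L >= 0L & -gb - 2L <= max_gap)
    if (all(ga >= 0L & ga <= max_gap) && (inc || dec))
      best <- length(idx)
  }
  best
}

# plant `copies` mutated copies of a consensus into unique backgrounds,
# producing named reads; returns list(reads, consensus)
planted_family_reads <- function(consensus, copies, divergence,
                                 flank = 250, id_prefix = "fam",
                                 gc = 0.45) {
  reads <- character(copies)
  names(reads) <- sprintf("%s_%03d.%s", id_prefix, seq_len(copies),
                          rep(c("f", "r"), length.out = copies))
  for (i in seq_len(copies)) {
    copy <- mutate_point(consensus, divergence)
    reads[i] <- paste0(rand_dna(flank, gc), copy, rand_dna(flank, gc))
  }
  reads
}

# phase-insensitive motif class: smallest rotation over motif and its
# reverse complement (used where maximal-run boundaries may shift phase)
rotation_classes <- function(motifs) {
  vapply(motifs, function(m) {
    rots <- function(x) {
      n <- nchar(x)
      vapply(seq_len(n), function(k)
        paste0(substr(x, k, n), substr(x, 1, k - 1)), character(1))
    }
    min(c(rots(m), rots(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

# simple point mutator (independent of the package's internal one)
mutate_point <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
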