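# Benchmark configurations shared by the acceptance suite.  Conditions
# mirror the surveyed corpus: the BES sample covers ~16.4% of the genome,
# novel families are recent (low internal divergence) and present in tens
# of copies, and known families are masked before self-comparison.

# SRE-mining benchmark: 20 novel families abundant enough to reach the
# support threshold, one 5-copy family that cannot, and two known
# (library) families that must be masked away first.  Repeat density
# (~19% novel families) and the support regime (tens of matching reads
# for typical families) echo a repeat-rich grass genome surveyed at
# sub-genomic depth.
sre_benchmark_config <- function(seed = 101) {
  novel <- data.frame(
    name = sprintf("SRE_true_%02d", 1:20),
    class_path = sprintf("SRE/SRE_true_%02d", 1:20),
    length = as.integer(round(seq(150, 250, length.out = 20))),
    copies = as.integer(round(seq(35, 60, length.out = 20))),
    divergence = 0.025, stringsAsFactors = FALSE)
  rare <- data.frame(name = "SRE_rare", class_path = "SRE/SRE_rare",
                     length = 200L, copies = 5L, divergence = 0.025,
                     stringsAsFactors = FALSE)
  known <- data.frame(
    name = c("Gypsy1", "EnSpm1"),
    class_path = c("Retroelements/LTR/Ty3-Gypsy", "DNATransposon/En-Spm"),
    length = c(800L, 500L), copies = c(25L, 18L),
    divergence = c(0.08, 0.05), stringsAsFactors = FALSE)
  sim_config(
    seed = seed, genome_length = 2e6,
    repeat_families = rbind(novel, rare, known),
    ssr_spec = default_ssr_spec()[0, ], gene_count = 0L,
    clone_count = 430L, error_rate = 0.005, contaminant_fraction = 0)
}

# genomic interval covered by each simulated read, from the clone truth
read_intervals <- function(bes) {
  cl <- bes$clones
  rows <- list()
  for (i in seq_len(nrow(cl))) {
    fid <- paste0(cl$clone_id[i], ".f")
    rid <- paste0(cl$clone_id[i], ".r")
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = c(fid, rid), seq_id = cl$seq_id[i],
      start = c(cl$start[i], cl$end[i] - nchar(bes$reads[[rid]]) + 1L),
      end = c(cl$start[i] + nchar(bes$reads[[fid]]) - 1L, cl$end[i]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Families discoverable under the support rule: reads that contain a FULL
# planted copy are guaranteed mutual matches, so a family with more than
# min_support such reads must surface.  (Reads overlapping only part of a
# copy may or may not share the required window with one another, so they
# do not count toward discoverability.)
qualifying_families <- function(sim, bes, min_reads = 7L) {
  ri <- read_intervals(bes)
  ri <- ri[ri$seq_id == names(sim$genome)[1], ]
  tr <- sim$truth$repeats
  out <- character()
  for (fam in unique(tr$family)) {
    copies <- tr[tr$family == fam, ]
    n_reads <- 0L
    for (j in seq_len(nrow(copies)))
      n_reads <- n_reads + sum(ri$start <= copies$start[j] &
                                 ri$end >= copies$end[j])
    if (n_reads >= min_reads) out <- c(out, fam)
  }
  out
}

# does a candidate consensus correspond to a planted family consensus?
matches_family <- function(consensus, family_seq,
                           min_identity = 90, min_len = 100) {
  h <- local_align(consensus, family_seq, seed_len = 10,
                   max_evalue = 1e-10)
  nrow(h) > 0 && any(h$pct_identity >= min_identity &
                       h$aln_len >= min_len)
}

# Rearranged-reference pairing benchmark: unique background genome with
# genes, one large inversion and one translocation to a second chromosome.
synteny_benchmark_config <- function(seed = 202) {
  sim_config(
    seed = seed, genome_length = 2e6,
    repeat_families = default_repeat_families()[0, ],
    ssr_spec = default_ssr_spec()[0, ], gene_count = 30L,
    clone_count = 150L, error_rate = 0.01, contaminant_fraction = 0,
    inversions = data.frame(n = 1, min_size = 2.5e5, max_size = 3.5e5),
    translocations = data.frame(n = 1, min_size = 1.5e5, max_size = 2.5e5))
}

# classify clones against the rearrangement breakpoints
clone_classes <- function(bes, breakpoints) {
  cl <- bes$clones
  spans <- vapply(seq_len(nrow(cl)), function(i)
    any(breakpoints > cl$start[i] & breakpoints < cl$end[i]), logical(1))
  list(spanning = cl$clone_id[spans], intact = cl$clone_id[!spans])
}
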