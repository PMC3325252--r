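# Deterministic simulator: genomes with planted repeat families, SSRs and
# GC-rich genes; BAC clones with inward-facing end reads and organellar
# contaminant clones; and a rearranged related reference with a lifted
# annotation and orthology table.  Everything is reproducible from the
# seed, and every planted feature is recorded in a truth table.

#' Simulation configuration
#'
#' Defaults describe the package's scaled test bed: a 2 Mbp genome at 45%
#' GC surveyed by BAC clones with ~40 kb inserts and Sanger-length end
#' reads (truncated normal, mean 761, sd 120, bounds 100-1000 bp, 1%
#' substitution error).
#'
#' @param seed integer seed.
#' @param genome_length genome length (bases).
#' @param background_gc background GC proportion.
#' @param repeat_families data.frame(name, class_path, length, copies,
#'   divergence): families planted as point-mutated copies of a random
#'   consensus.
#' @param ssr_spec data.frame(motif, count, min_units, max_units).
#' @param gene_count,peptide_length genes planted as back-translated
#'   random peptides with GC-biased codon choice.
#' @param coding_gc_bias strength of the G/C-ending codon preference.
#' @param clone_count clones to sample.
#' @param insert_mean,insert_sd,insert_min,insert_max insert-size model
#'   (truncated normal, bases).
#' @param read_mean,read_sd,read_min,read_max read-length model (truncated
#'   normal, bases).
#' @param error_rate per-base substitution error rate of the reads.
#' @param contaminant_fraction fraction of clones drawn from organellar
#'   sequence.
#' @param organellar_length length of each simulated organellar genome.
#' @param inversions,translocations,deletions data.frames (n draws come
#'   from min_size/max_size columns) describing the related reference.
#' @return list of class "sim_config".
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       background_gc = 0.45,
                       repeat_families = default_repeat_families(),
                       ssr_spec = default_ssr_spec(),
                       gene_count = 40L,
                       peptide_length = c(100L, 300L),
                       coding_gc_bias = 1.5,
                       clone_count = 1500L,
                       insert_mean = 40000, insert_sd = 8000,
                       insert_min = 20000, insert_max = 80000,
                       read_mean = 761, read_sd = 120,
                       read_min = 100, read_max = 1000,
                       error_rate = 0.01,
                       contaminant_fraction = 0.005,
                       organellar_length = 120000,
                       inversions = data.frame(n = 1, min_size = 2e5,
                                               max_size = 3e5),
                       translocations = data.frame(n = 1, min_size = 1e5,
                                                   max_size = 2e5),
                       deletions = data.frame(n = 0, min_size = 0,
                                              max_size = 0)) {
  cfg <- as.list(environment())
  stopifnot(genome_length > 0, background_gc > 0, background_gc < 1,
            insert_mean < genome_length, error_rate >= 0, error_rate < 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1)
  structure(cfg, class = "sim_config")
}

default_repeat_families <- function() {
  data.frame(
    name = c("Gypsy1", "Copia1", "LINE1", "EnSpm1", "Harbinger1"),
    class_path = c("Retroelements/LTR/Ty3-Gypsy",
                   "Retroelements/LTR/Ty1-Copia",
                   "Retroelements/LINE/L1",
                   "DNATransposon/En-Spm",
                   "DNATransposon/Tourist-Harbinger"),
    length = c(800L, 700L, 600L, 500L, 300L),
    copies = c(60L, 40L, 25L, 30L, 20L),
    divergence = c(0.08, 0.08, 0.1, 0.05, 0.05),
    stringsAsFactors = FALSE)
}

# trimer-dominant, GC-rich mix echoing grass-genome SSR composition
default_ssr_spec <- function() {
  data.frame(motif = c("A", "AG", "AT", "GCC", "CGC", "AAG", "ACGT"),
             count = c(60L, 45L, 30L, 115L, 55L, 40L, 15L),
             min_units = c(12L, 8L, 8L, 5L, 5L, 5L, 4L),
             max_units = c(20L, 15L, 15L, 10L, 10L, 10L, 7L),
             stringsAsFactors = FALSE)
}

#' Random DNA
#' @param n length (bases).
#' @param gc GC proportion.
#' @return a single DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# point-mutate a sequence at the given substitution rate
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# back-translate a peptide choosing codons with a G/C-ending preference
back_translate <- function(peptide, gc_bias = 1.5) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), code)
  aas <- strsplit(peptide, "")[[1]]
  codons <- vapply(aas, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) return("NNN")
    gc_n <- nchar(gsub("[^GC]", "", opts))
    sample(opts, 1, prob = exp(gc_bias * gc_n))
  }, character(1))
  paste(codons, collapse = "")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# draw a non-overlapping placement of `len` against occupied IRanges
place_interval <- function(len, genome_length, occupied, max_tries = 2000) {
  if (len > genome_length)
    stop("requested planting exceeds the genome length")
  for (t in seq_len(max_tries)) {
    start <- sample.int(genome_length - len + 1L, 1)
    cand <- IRanges::IRanges(start, start + len - 1L)
    if (length(occupied) == 0 ||
        !any(IRanges::overlapsAny(cand, occupied))) return(cand)
  }
  stop("could not place a ", len, " bp feature without overlap; ",
       "the genome is too crowded")
}

#' Simulate a genome with planted features and truth tables
#'
#' @param config a [sim_config()].
#' @return list with \code{genome} (named character, "chr1"),
#'   \code{truth} (repeats, ssrs, genes data.frames) and \code{families}
#'   (family consensus sequences).
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  G <- as.integer(config$genome_length)
  fam <- config$repeat_families
  total_plant <- sum(fam$length * fam$copies) +
    sum(nchar(config$ssr_spec$motif) * config$ssr_spec$max_units *
          config$ssr_spec$count) +
    config$gene_count * (max(config$peptide_length) * 3 + 3)
  if (total_plant >= G)
    stop("requested plantings exceed genome length")
  chars <- strsplit(random_dna(G, config$background_gc), "")[[1]]
  occupied <- IRanges::IRanges()
  consensi <- character(nrow(fam))
  names(consensi) <- fam$name
  rep_rows <- list(); ssr_rows <- list(); gene_rows <- list()
  if (nrow(fam) > 0) for (f in seq_len(nrow(fam))) {
    consensi[f] <- random_dna(fam$length[f], config$background_gc)
    for (cp in seq_len(fam$copies[f])) {
      copy <- mutate_seq(consensi[f], fam$divergence[f])
      strand <- sample(c("+", "-"), 1)
      planted <- if (strand == "+") copy else revcomp(copy)
      iv <- place_interval(nchar(planted), G, occupied)
      occupied <- c(occupied, iv)
      s <- IRanges::start(iv)
      chars[s:(s + nchar(planted) - 1L)] <- strsplit(planted, "")[[1]]
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        family = fam$name[f], class_path = fam$class_path[f],
        start = s, end = s + nchar(planted) - 1L, strand = strand,
        planted_seq = planted, stringsAsFactors = FALSE)
    }
  }
  spec <- config$ssr_spec
  if (nrow(spec) > 0) for (si in seq_len(nrow(spec))) {
    for (cp in seq_len(spec$count[si])) {
      units <- sample(spec$min_units[si]:spec$max_units[si], 1)
      run <- strrep(spec$motif[si], units)
      iv <- place_interval(nchar(run) + 2L, G, occupied)
      occupied <- c(occupied, iv)
      # plant with non-repeat flanks so the run stays maximal
      s <- IRanges::start(iv) + 1L
      chars[(s - 1L)] <- flank_base(spec$motif[si], last = TRUE)
      chars[s:(s + nchar(run) - 1L)] <- strsplit(run, "")[[1]]
      chars[s + nchar(run)] <- flank_base(spec$motif[si], last = FALSE)
      ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
        motif = spec$motif[si], start = s, end = s + nchar(run) - 1L,
        units = units, stringsAsFactors = FALSE)
    }
  }
  if (config$gene_count > 0) for (gi in seq_len(config$gene_count)) {
    plen <- sample(config$peptide_length[1]:config$peptide_length[2], 1)
    pep <- random_peptide(plen)
    cds <- paste0(back_translate(pep, config$coding_gc_bias), "TAA")
    strand <- sample(c("+", "-"), 1)
    planted <- if (strand == "+") cds else revcomp(cds)
    iv <- place_interval(nchar(planted), G, occupied)
    occupied <- c(occupied, iv)
    s <- IRanges::start(iv)
    chars[s:(s + nchar(planted) - 1L)] <- strsplit(planted, "")[[1]]
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = sprintf("gene%03d", gi), start = s,
      end = s + nchar(planted) - 1L, strand = strand, peptide = pep,
      stringsAsFactors = FALSE)
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  list(genome = c(chr1 = paste(chars, collapse = "")),
       truth = list(
         repeats = bind(rep_rows, data.frame(
           family = character(), class_path = character(),
           start = integer(), end = integer(), strand = character(),
           planted_seq = character(), stringsAsFactors = FALSE)),
         ssrs = bind(ssr_rows, data.frame(
           motif = character(), start = integer(), end = integer(),
           units = integer(), stringsAsFactors = FALSE)),
         genes = bind(gene_rows, data.frame(
           gene_id = character(), start = integer(), end = integer(),
           strand = character(), peptide = character(),
           stringsAsFactors = FALSE))),
       families = consensi)
}

# a base that cannot extend a run of `motif` on the given side
flank_base <- function(motif, last) {
  b <- substr(motif, if (last) nchar(motif) else 1L,
              if (last) nchar(motif) else 1L)
  setdiff(c("A", "C", "G", "T"), b)[1]
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate BAC clones and end reads from a genome
#'
#' Clone inserts are placed uniformly; each contributes two inward-facing
#' end reads (the reverse end is reverse-complemented), with truncated-
#' normal lengths and per-base substitution errors.  A configured fraction
#' of clones is drawn from simulated organellar sequence instead.
#'
#' @param sim result of [simulate_genome()] (or a list with a
#'   \code{genome} element).
#' @param config the [sim_config()] used for the genome.
#' @param library_id prefix for clone and read ids.
#' @return list with \code{reads} (named character) and \code{clones}
#'   (clone_id, seq_id, start, end, insert_len, contaminant).
#' @export
simulate_bes <- function(sim, config = sim_config(),
                         library_id = "SimA") {
  set.seed(config$seed + 1L)
  genome <- sim$genome[[1]]
  G <- nchar(genome)
  if (config$insert_mean >= G) stop("insert mean must be below genome length")
  n <- config$clone_count
  organellar <- random_dna(config$organellar_length, 0.38)
  inserts <- round(rtrunc_norm(n, config$insert_mean, config$insert_sd,
                               config$insert_min,
                               min(config$insert_max, G)))
  contaminant <- runif(n) < config$contaminant_fraction
  reads <- character(0)
  clones <- vector("list", n)
  for (i in seq_len(n)) {
    L <- inserts[i]
    src <- if (contaminant[i]) organellar else genome
    src_len <- nchar(src)
    L <- min(L, src_len)
    start <- sample.int(src_len - L + 1L, 1)
    insert <- substr(src, start, start + L - 1L)
    rl <- round(rtrunc_norm(2, config$read_mean, config$read_sd,
                            config$read_min, config$read_max))
    rl <- pmin(rl, L)
    fwd <- substr(insert, 1L, rl[1])
    rev <- revcomp(substr(insert, L - rl[2] + 1L, L))
    if (config$error_rate > 0) {
      fwd <- mutate_seq(fwd, config$error_rate)
      rev <- mutate_seq(rev, config$error_rate)
    }
    clone_id <- sprintf("%s_%05d", library_id, i)
    reads[paste0(clone_id, ".f")] <- fwd
    reads[paste0(clone_id, ".r")] <- rev
    clones[[i]] <- data.frame(
      clone_id = clone_id,
      seq_id = if (contaminant[i]) "organellar" else names(sim$genome)[1],
      start = start, end = start + L - 1L, insert_len = L,
      contaminant = contaminant[i], stringsAsFactors = FALSE)
  }
  list(reads = reads, clones = do.call(rbind, clones),
       organellar = c(organellar = organellar))
}

#' Simulate a rearranged related reference
#'
#' Draws non-overlapping inversion, translocation and deletion intervals
#' on the source genome, builds the related reference from the resulting
#' blocks (translocated blocks move to a second chromosome), lifts the
#' gene annotation through the rearrangements (genes spanning a breakpoint
#' are dropped) and records every operation.
#'
#' @param sim result of [simulate_genome()].
#' @param config the [sim_config()].
#' @return list with \code{reference} (named character: chrA and, when
#'   translocations exist, chrB), \code{orthology} (surviving gene pairs
#'   with source and target coordinates, strands, and rank positions
#'   pos_a/pos_b for collinearity analysis), \code{ledger} (one row per
#'   operation) and \code{breakpoints} (source coordinates).
#' @export
simulate_related_reference <- function(sim, config = sim_config()) {
  set.seed(config$seed + 2L)
  genome <- sim$genome[[1]]
  G <- nchar(genome)
  draw_ops <- function(spec, op) {
    n <- if (nrow(spec) > 0) spec$n[1] else 0L
    if (n == 0) return(NULL)
    data.frame(op = op,
               size = round(runif(n, spec$min_size[1], spec$max_size[1])))
  }
  ops <- rbind(draw_ops(config$inversions, "inversion"),
               draw_ops(config$translocations, "translocation"),
               draw_ops(config$deletions, "deletion"))
  occupied <- IRanges::IRanges()
  if (!is.null(ops) && nrow(ops) > 0) {
    ops$start <- NA_integer_
    for (i in seq_len(nrow(ops))) {
      iv <- tryCatch(place_interval(ops$size[i], G, occupied),
                     error = function(e)
                       stop("could not draw non-overlapping ",
                            "rearrangements; reduce their number or size"))
      occupied <- c(occupied, iv)
      ops$start[i] <- IRanges::start(iv)
    }
    ops$end <- ops$start + ops$size - 1L
    ops <- ops[order(ops$start), , drop = FALSE]
  }
  # partition the source into blocks at operation boundaries
  bounds <- sort(unique(c(1L,
                          if (!is.null(ops)) c(ops$start, ops$end + 1L),
                          G + 1L)))
  blocks <- data.frame(src_start = bounds[-length(bounds)],
                       src_end = bounds[-1] - 1L)
  blocks$op <- "identity"
  if (!is.null(ops) && nrow(ops) > 0)
    for (i in seq_len(nrow(ops))) {
      hit <- blocks$src_start == ops$start[i] & blocks$src_end == ops$end[i]
      blocks$op[hit] <- ops$op[i]
    }
  chrA <- character(); chrB <- character()
  posA <- 0L; posB <- 0L
  lift <- list()
  for (i in seq_len(nrow(blocks))) {
    seg <- substr(genome, blocks$src_start[i], blocks$src_end[i])
    w <- nchar(seg)
    if (blocks$op[i] == "deletion") {
      lift[[i]] <- data.frame(target_chr = NA, target_start = NA,
                              orientation = NA)
      next
    }
    if (blocks$op[i] == "translocation") {
      chrB <- c(chrB, seg)
      lift[[i]] <- data.frame(target_chr = "chrB",
                              target_start = posB + 1L, orientation = "+")
      posB <- posB + w
      next
    }
    if (blocks$op[i] == "inversion") seg <- revcomp(seg)
    chrA <- c(chrA, seg)
    lift[[i]] <- data.frame(target_chr = "chrA", target_start = posA + 1L,
                            orientation = if (blocks$op[i] == "inversion")
                              "-" else "+")
    posA <- posA + w
  }
  blocks <- cbind(blocks, do.call(rbind, lift))
  reference <- c(chrA = paste(chrA, collapse = ""))
  if (posB > 0) reference["chrB"] <- paste(chrB, collapse = "")
  genes <- sim$truth$genes
  orth <- list()
  if (nrow(genes) > 0) for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    blk <- which(blocks$src_start <= g$start & blocks$src_end >= g$end)
    if (length(blk) != 1) next               # spans a breakpoint
    b <- blocks[blk, ]
    if (b$op == "deletion") next
    if (b$orientation == "+") {
      ns <- b$target_start + (g$start - b$src_start)
      ne <- b$target_start + (g$end - b$src_start)
      nstrand <- g$strand
    } else {
      ns <- b$target_start + (b$src_end - g$end)
      ne <- b$target_start + (b$src_end - g$start)
      nstrand <- if (g$strand == "+") "-" else "+"
    }
    orth[[length(orth) + 1L]] <- data.frame(
      gene_id = g$gene_id, src_start = g$start, src_end = g$end,
      src_strand = g$strand, ref_seq = b$target_chr, ref_start = ns,
      ref_end = ne, ref_strand = nstrand, stringsAsFactors = FALSE)
  }
  orthology <- if (length(orth)) do.call(rbind, orth) else
    data.frame(gene_id = character(), src_start = integer(),
               src_end = integer(), src_strand = character(),
               ref_seq = character(), ref_start = integer(),
               ref_end = integer(), ref_strand = character(),
               stringsAsFactors = FALSE)
  if (nrow(orthology) > 0) {
    orthology <- orthology[order(orthology$src_start), , drop = FALSE]
    orthology$pos_a <- seq_len(nrow(orthology))
    ord_b <- order(orthology$ref_seq, orthology$ref_start)
    orthology$pos_b[ord_b] <- seq_len(nrow(orthology))
  }
  breakpoints <- if (!is.null(ops) && nrow(ops) > 0)
    sort(unique(c(ops$start - 1L, ops$end))) else integer()
  breakpoints <- breakpoints[breakpoints >= 1 & breakpoints < G]
  list(reference = reference, orthology = orthology, ledger = blocks,
       breakpoints = breakpoints)
}
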