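# Domain containers are plain data frames: a BES set is a data.frame with
# columns read_id, clone_id, end, library_id, sequence, length.  Sequences
# travel as named character vectors (uppercase ACGTN; lowercase = soft mask)
# so that masking state survives round trips that DNAStringSet would erase.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and any IUPAC code other than A/C/G/T/N is
#' normalized to N (with a warning); Sanger reads routinely carry ambiguity
#' calls and downstream stages only understand the 5-letter alphabet.
#'
#' @param path path to a FASTA file.
#' @param preserve_case keep lowercase (soft-masked) letters as-is instead
#'   of uppercasing.  Ambiguity normalization still applies.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, preserve_case = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      # locate the offending line for a useful message
      lines <- readLines(path, warn = FALSE)
      if (length(lines) == 0) stop("FASTA parse error in ", path,
                                   ": file is empty", call. = FALSE)
      first <- which(nzchar(trimws(lines)))[1]
      if (is.na(first) || !startsWith(lines[first], ">"))
        stop("FASTA parse error in ", path, " at line ",
             if (is.na(first)) 1 else first,
             ": expected a '>' header", call. = FALSE)
      stop("FASTA parse error in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (length(set) == 0)
    stop("FASTA parse error in ", path,
         ": file is empty or contains no records")
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (!preserve_case) seqs <- toupper(seqs)
  normalize_alphabet(seqs)
}

# map every letter outside {A,C,G,T,N} (case-insensitively) to N, warning once
normalize_alphabet <- function(seqs) {
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contained IUPAC ambiguity codes; ",
            "normalized to N")
    up <- "RYSWKMBDHVUEFIJLOPQXZ"
    lo <- tolower(up)
    seqs[bad] <- chartr(paste0(up, lo),
                        paste0(strrep("N", nchar(up)),
                               strrep("n", nchar(lo))),
                        seqs[bad])
    seqs[bad] <- gsub("[^ACGTNacgtn]", "N", seqs[bad])
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (case is preserved, so soft-masked
#'   output survives).
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement, preserving mask case
#'
#' @param seqs character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seqs) {
  vapply(seqs, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           intToUtf8(rev(utf8ToInt(s))))
  }, character(1), USE.NAMES = !is.null(names(seqs)))
}

#' Build a BES record table from named sequences
#'
#' Read ids are parsed into clone and end with a configurable pattern; the
#' default expects a trailing \code{.f} / \code{.r} (forward/reverse).
#'
#' @param seqs named character vector of reads.
#' @param end_pattern regex whose first capture group is the end letter;
#'   stripped from the id to obtain the clone id.
#' @param forward,reverse end letters denoting the forward and reverse read.
#' @param library_pattern regex whose first capture group, applied to the
#'   clone id, yields the library id (NA when it does not match).
#' @return data.frame with columns read_id, clone_id, end, library_id,
#'   sequence, length.
#' @export
bes_records <- function(seqs, end_pattern = "\\.([fr])$",
                        forward = "f", reverse = "r",
                        library_pattern = "^([^_]+)_") {
  if (length(seqs) == 0)
    return(data.frame(read_id = character(), clone_id = character(),
                      end = character(), library_id = character(),
                      sequence = character(), length = integer(),
                      stringsAsFactors = FALSE))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all reads must be named")
  m <- regmatches(ids, regexec(end_pattern, ids))
  letter <- vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_,
                   character(1))
  if (anyNA(letter))
    stop("read id(s) not parseable by end pattern: ",
         paste(head(ids[is.na(letter)], 5), collapse = ", "))
  clone <- sub(end_pattern, "", ids)
  end <- ifelse(letter == forward, "forward",
                ifelse(letter == reverse, "reverse", NA))
  if (anyNA(end)) stop("unknown end letter in read id(s)")
  lm <- regmatches(clone, regexec(library_pattern, clone))
  lib <- vapply(lm, function(x) if (length(x) >= 2) x[2] else NA_character_,
                character(1))
  data.frame(read_id = ids, clone_id = clone, end = end, library_id = lib,
             sequence = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Pair BAC-end reads by clone
#'
#' @param records a BES record table from [bes_records()].
#' @return list with \code{pairs} (clone_id, forward_id, reverse_id),
#'   \code{unpaired} read ids, and \code{paired_fraction}: the percentage of
#'   reads belonging to clones with both ends present.
#' @export
pair_bes <- function(records) {
  if (nrow(records) == 0)
    return(list(pairs = data.frame(clone_id = character(),
                                   forward_id = character(),
                                   reverse_id = character(),
                                   stringsAsFactors = FALSE),
                unpaired = character(), paired_fraction = 0))
  key <- paste(records$clone_id, records$end)
  if (anyDuplicated(key))
    stop("duplicate (clone, end) combinations: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  fwd <- records[records$end == "forward", ]
  rev <- records[records$end == "reverse", ]
  both <- intersect(fwd$clone_id, rev$clone_id)
  pairs <- data.frame(
    clone_id = both,
    forward_id = fwd$read_id[match(both, fwd$clone_id)],
    reverse_id = rev$read_id[match(both, rev$clone_id)],
    stringsAsFactors = FALSE)
  unpaired <- records$read_id[!records$clone_id %in% both]
  list(pairs = pairs, unpaired = unpaired,
       paired_fraction = 100 * (nrow(records) - length(unpaired)) /
         nrow(records))
}

# ---------------------------------------------------------------------------
# GFF3 and tabular alignment I/O.  Feature tables use 1-based inclusive
# coordinates throughout (the IRanges convention), so GFF3 export needs no
# coordinate shift.
# ---------------------------------------------------------------------------

GFF3_RESERVED <- "[;=&,\t\n]"

#' Write features to GFF3
#'
#' @param features a [GenomicRanges::GRanges] whose metadata columns include
#'   \code{type}; remaining metadata columns become attributes.
#' @param path output path.
#' @param source source tag for column 2.
#' @export
write_gff3 <- function(features, path, source = "bessurvey") {
  stopifnot(is(features, "GRanges"))
  mc <- S4Vectors::mcols(features)
  attr_cols <- setdiff(colnames(mc), c("type", "score", "phase"))
  for (col in attr_cols) {
    vals <- as.character(mc[[col]])
    bad <- grepl(GFF3_RESERVED, vals)
    if (any(bad))
      stop("attribute '", col, "' contains unescaped reserved characters ",
           "in ", sum(bad), " feature(s)")
  }
  S4Vectors::mcols(features)$source <- source
  rtracklayer::export(features, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file as GRanges
#'
#' @param path GFF3 path.
#' @return a [GenomicRanges::GRanges].
#' @export
read_gff3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

BLAST6_COLS <- c("query_id", "subject_id", "pct_identity", "aln_len",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bit_score")

#' Read a 12-column tabular alignment file (BLAST outfmt 6 field order)
#'
#' @param path tab-separated file with no header.
#' @return data.frame of alignment hits.
#' @export
read_hits <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12)
    stop("expected 12 tab-separated columns, found ", ncol(df))
  names(df) <- BLAST6_COLS
  df
}

#' Write alignment hits as 12-column tabular
#'
#' @param hits data.frame with the columns of [read_hits()].
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  write.table(hits[, BLAST6_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# empty hit table with the canonical column layout
empty_hits <- function() {
  df <- data.frame(query_id = character(), subject_id = character(),
                   pct_identity = numeric(), aln_len = integer(),
                   mismatches = integer(), gap_opens = integer(),
                   q_start = integer(), q_end = integer(),
                   s_start = integer(), s_end = integer(),
                   evalue = numeric(), bit_score = numeric(),
                   stringsAsFactors = FALSE)
  df
}
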