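make_library <- function() {
  set.seed(321)
  data.frame(
    name = c("Gypsy1", "EnSpm1"),
    class_path = c("Retroelements/LTR/Ty3-Gypsy", "DNATransposon/En-Spm"),
    sequence = c(rand_dna(400), rand_dna(350)),
    stringsAsFactors = FALSE)
}

test_that("an exact element copy yields one correctly classed hit", {
  lib <- make_library()
  set.seed(1)
  reads <- c(r1 = paste0(rand_dna(100), lib$sequence[1], rand_dna(100)))
  ann <- annotate_repeats(reads, lib)
  expect_equal(nrow(ann$hits), 1L)
  expect_identical(ann$hits$name, "Gypsy1")
  expect_identical(ann$hits$class_path, "Retroelements/LTR/Ty3-Gypsy")
  expect_equal(ann$hits$merged_from, 1L)
  expect_equal(c(ann$hits$read_start, ann$hits$read_end), c(101L, 500L))
  # soft masking lowercases exactly the hit span
  expect_identical(substr(ann$masked[["r1"]], 101, 500),
                   tolower(lib$sequence[1]))
  expect_identical(substr(ann$masked[["r1"]], 1, 100),
                   substr(reads[["r1"]], 1, 100))
  expect_error(annotate_repeats(reads, lib[0, ]), "empty")
})

test_that("fragments split by an insertion count as one element", {
  lib <- make_library()
  set.seed(2)
  elem <- lib$sequence[1]
  reads <- c(r1 = paste0(rand_dna(80), substr(elem, 1, 200),
                         rand_dna(60), substr(elem, 201, 400),
                         rand_dna(80)))
  ann <- annotate_repeats(reads, lib, merge_gap_read = 100)
  expect_equal(nrow(ann$hits), 1L)
  expect_gte(ann$hits$merged_from, 1L)
  # spanning interval covers both fragments
  expect_lte(ann$hits$read_start, 81L)
  expect_gte(ann$hits$read_end, 540L)
})

test_that("minus-strand copies are found and merging is order-independent", {
  lib <- make_library()
  set.seed(3)
  reads <- c(r1 = paste0(rand_dna(90), revcomp(lib$sequence[2]),
                         rand_dna(90)))
  ann <- annotate_repeats(reads, lib)
  expect_equal(nrow(ann$hits), 1L)
  expect_identical(ann$hits$strand, "-")
  expect_identical(ann$hits$name, "EnSpm1")
})

test_that("diverged planted copies are recovered with correct classes", {
  lib <- make_library()
  set.seed(4)
  n <- 40
  reads <- character(n)
  truth <- character(n)
  for (i in seq_len(n)) {
    e <- sample(1:2, 1)
    copy <- mutate_point(lib$sequence[e], 0.15)  # 85% identity
    if (runif(1) < 0.5) copy <- revcomp(copy)
    reads[i] <- paste0(rand_dna(120), copy, rand_dna(120))
    truth[i] <- lib$name[e]
  }
  names(reads) <- sprintf("r%02d", seq_len(n))
  ann <- annotate_repeats(reads, lib, min_identity = 70)
  per_read <- ann$hits[!duplicated(ann$hits$read_id), ]
  expect_gte(nrow(per_read), ceiling(0.95 * n))
  hit_names <- setNames(per_read$name, per_read$read_id)
  common <- intersect(names(hit_names), names(reads))
  expect_identical(unname(hit_names[names(reads)[seq_len(n)] ]),
                   truth)
})

test_that("masking is idempotent: re-annotating masked reads adds nothing", {
  lib <- make_library()
  set.seed(5)
  reads <- c(r1 = paste0(rand_dna(100), lib$sequence[1], rand_dna(50),
                         lib$sequence[2], rand_dna(100)))
  ann1 <- annotate_repeats(reads, lib)
  expect_equal(nrow(ann1$hits), 2L)
  hard <- mask_reads(reads, ann1$hits, "hard")
  ann2 <- annotate_repeats(hard, lib)
  expect_equal(nrow(ann2$hits), 0L)
})

test_that("low-complexity windows flag homopolymers and dimer runs", {
  runs <- c(r1 = strrep("A", 200),
            r2 = strrep("AT", 100))
  lc <- detect_low_complexity(runs)
  for (id in names(runs)) {
    iv <- lc[lc$read_id == id, ]
    expect_equal(nrow(iv), 1L)
    covered <- iv$end - iv$start + 1
    expect_gte(covered / nchar(runs[[id]]), 0.9)
  }
  set.seed(6)
  rnd <- c(r3 = rand_dna(1000))
  expect_equal(nrow(detect_low_complexity(rnd)), 0L)
})

test_that("summaries aggregate classes hierarchically without double counting", {
  hits <- data.frame(
    read_id = c("r1", "r1", "r2", "r3"),
    name = c("Gypsy1", "Gypsy1", "Copia1", "EnSpm1"),
    class_path = c("Retroelements/LTR/Ty3-Gypsy",
                   "Retroelements/LTR/Ty3-Gypsy",
                   "Retroelements/LTR/Ty1-Copia",
                   "DNATransposon/En-Spm"),
    read_start = c(1L, 151L, 1L, 1L),
    read_end = c(200L, 300L, 100L, 50L),
    strand = "+", pct_identity = 90, merged_from = 1L,
    stringsAsFactors = FALSE)
  s <- summarize_repeats(hits, 1000)
  ltr <- s[s$class_path == "Retroelements/LTR", ]
  expect_equal(ltr$element_count, 3L)
  expect_equal(ltr$bases, 400)             # r1 union 300 + r2 100
  retro <- s[s$class_path == "Retroelements", ]
  expect_equal(retro$bases, 400)
  expect_equal(retro$pct, 40)
  # child bases never exceed the parent's
  for (cp in s$class_path) {
    parents <- s$class_path[startsWith(cp, paste0(s$class_path, "/"))]
    for (pa in parents)
      expect_lte(s$bases[s$class_path == cp],
                 s$bases[s$class_path == pa])
  }
  inter <- attr(s, "interspersed")
  expect_equal(inter$bases, 450)
  expect_error(summarize_repeats(hits, 0), "positive")
})

test_that("overlapping hits within a class are unioned for base counts", {
  hits <- data.frame(read_id = "r1", name = "Gypsy1",
                     class_path = "Retroelements/LTR/Ty3-Gypsy",
                     read_start = c(1L, 51L), read_end = c(100L, 150L),
                     strand = "+", pct_identity = 90, merged_from = 1L,
                     stringsAsFactors = FALSE)
  s <- summarize_repeats(hits, 1000)
  expect_equal(s$bases[s$class_path == "Retroelements"], 150)
})

test_that("published census ratios are recovered from a class table", {
  census <- data.frame(
    class_path = c("Retroelements", "Retroelements/LTR",
                   "Retroelements/LTR/Ty1-Copia",
                   "Retroelements/LTR/Ty3-Gypsy",
                   "DNATransposon", "DNATransposon/En-Spm"),
    element_count = c(178318L, 161196L, 50870L, 108785L, 63616L, 22287L),
    bases = c(64563658, 58196935, 18995037, 38941535, 14149503, 6169405))
  r <- repeat_summary_ratios(census, 263.2e6, decimals = 2)
  expect_equal(round(r$class1_share_pct, 1), 73.7)
  expect_equal(round(r$class2_share_pct, 1), 26.3)
  expect_equal(round(r$ltr_share_pct, 1), 90.4)
  expect_equal(r$retro_fraction_pct, 24.53)
  expect_equal(round(r$enspm_share_pct, 0), 35)
  expect_equal(round(r$gypsy_copia_ratio), 2)
})
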