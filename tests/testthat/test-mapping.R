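fake_hit <- function(query_id = "c1.f", subject_id = "chr1",
                     pct_identity = 90, evalue = 1e-30, bit_score = 100,
                     q_start = 1L, q_end = 600L, s_start = 1000L,
                     s_end = 1599L) {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = pct_identity, aln_len = abs(q_end - q_start) + 1L,
             mismatches = 0L, gap_opens = 0L, q_start = q_start,
             q_end = q_end, s_start = s_start, s_end = s_end,
             evalue = evalue, bit_score = bit_score,
             stringsAsFactors = FALSE)
}

test_that("placement filters enforce identity, E-value and coverage jointly", {
  lens <- c(c1.f = 1000)
  expect_equal(nrow(filter_hits(fake_hit(pct_identity = 80,
                                         evalue = 1e-30), lens)), 1L)
  expect_equal(nrow(filter_hits(fake_hit(pct_identity = 70,
                                         evalue = 1e-30), lens)), 0L)
  expect_equal(nrow(filter_hits(fake_hit(pct_identity = 80,
                                         evalue = 1e-10), lens)), 0L)
  # coverage is strict: exactly 50% fails, just over passes
  expect_equal(nrow(filter_hits(fake_hit(q_end = 500L), lens)), 0L)
  expect_equal(nrow(filter_hits(fake_hit(q_end = 501L), lens)), 1L)
  expect_error(filter_hits(fake_hit(query_id = "nope"), lens), "unknown")
  # randomly corrupted tables: every surviving row satisfies all bounds
  set.seed(61)
  rows <- do.call(rbind, replicate(200, fake_hit(
    pct_identity = runif(1, 50, 100),
    evalue = 10^runif(1, -40, -5),
    q_end = sample(200:1000, 1)), simplify = FALSE))
  kept <- filter_hits(rows, lens)
  expect_true(all(kept$pct_identity >= 75 & kept$evalue < 1e-20 &
                    kept$coverage > 0.5))
  dropped <- nrow(rows) - nrow(kept)
  expect_gt(dropped, 0)
})

test_that("best placement is score-sorted with deterministic tie-breaks", {
  hits <- rbind(fake_hit(bit_score = 100, subject_id = "chr2"),
                fake_hit(bit_score = 90, subject_id = "chr1"))
  best <- best_placement(hits)
  expect_equal(best$bit_score, 100)
  # exact tie: lexicographically smaller subject wins
  tie <- rbind(fake_hit(bit_score = 100, subject_id = "chr2"),
               fake_hit(bit_score = 100, subject_id = "chr1"))
  expect_identical(best_placement(tie)$subject_id, "chr1")
  # then leftmost coordinate
  tie2 <- rbind(fake_hit(s_start = 5000L, s_end = 5599L),
                fake_hit(s_start = 100L, s_end = 699L))
  expect_equal(best_placement(tie2)$s_start, 100L)
  single <- fake_hit()
  expect_equal(best_placement(single), single)
})

test_that("pair calling applies the insert-span rule", {
  pairs <- data.frame(clone_id = "c1", forward_id = "c1.f",
                      reverse_id = "c1.r", stringsAsFactors = FALSE)
  pl <- rbind(fake_hit(query_id = "c1.f", s_start = 100000L,
                       s_end = 100600L),
              fake_hit(query_id = "c1.r", s_start = 450000L,
                       s_end = 449400L))
  res <- call_pairs(pl, pairs, max_insert = 5e5)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$span, 450000 - 100000 + 1)
  expect_identical(unname(res$category[c("c1.f", "c1.r")]),
                   c("paired", "paired"))
  # 700 kb apart: two singlets
  far <- rbind(fake_hit(query_id = "c1.f", s_start = 1000L,
                        s_end = 1600L),
               fake_hit(query_id = "c1.r", s_start = 700000L,
                        s_end = 700600L))
  res2 <- call_pairs(far, pairs, max_insert = 5e5)
  expect_equal(nrow(res2$pairs), 0L)
  expect_setequal(res2$singlets, c("c1.f", "c1.r"))
  # different chromosomes: singlets
  diffc <- rbind(fake_hit(query_id = "c1.f", subject_id = "chr1"),
                 fake_hit(query_id = "c1.r", subject_id = "chr2"))
  expect_equal(nrow(call_pairs(diffc, pairs)$pairs), 0L)
  # read-order permutation leaves the result unchanged
  res3 <- call_pairs(pl[2:1, ], pairs, max_insert = 5e5)
  expect_equal(res3$pairs, res$pairs)
})

test_that("strict orientation requires convergent ends", {
  pairs <- data.frame(clone_id = "c1", forward_id = "c1.f",
                      reverse_id = "c1.r", stringsAsFactors = FALSE)
  convergent <- rbind(
    fake_hit(query_id = "c1.f", s_start = 1000L, s_end = 1600L),
    fake_hit(query_id = "c1.r", s_start = 40000L, s_end = 39400L))
  expect_equal(nrow(call_pairs(convergent, pairs,
                               strict_orientation = TRUE)$pairs), 1L)
  same_dir <- rbind(
    fake_hit(query_id = "c1.f", s_start = 1000L, s_end = 1600L),
    fake_hit(query_id = "c1.r", s_start = 39400L, s_end = 40000L))
  expect_equal(nrow(call_pairs(same_dir, pairs,
                               strict_orientation = TRUE)$pairs), 0L)
})

test_that("mate rescue finds the mate within the window only", {
  set.seed(62)
  ref <- c(chr1 = rand_dna(300000))
  mate <- substr(ref[["chr1"]], 200000, 200700)
  anchor <- fake_hit(query_id = "c1.f", s_start = 20000L, s_end = 20600L)
  got <- rescue_mate(mate, "c1.r", anchor, ref, max_insert = 2e5)
  expect_false(is.null(got))
  expect_equal(got$s_start, 200000L)
  expect_gte(got$pct_identity, 99)
  # out of window: no rescue
  none <- rescue_mate(mate, "c1.r", anchor, ref, max_insert = 5e4)
  expect_null(none)
  # a mate from elsewhere entirely: no rescue
  alien <- rand_dna(700)
  expect_null(rescue_mate(alien, "c1.r", anchor, ref, max_insert = 2e5))
})

test_that("coding overlap fractions are exact on hand-built annotation", {
  ann <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = c(1000, 5000, 9000),
                              width = 1000))
  S4Vectors::mcols(ann)$type <- "CDS"
  pl <- rbind(fake_hit(query_id = "a", s_start = 1100L, s_end = 1700L),
              fake_hit(query_id = "b", s_start = 5200L, s_end = 5800L),
              fake_hit(query_id = "c", s_start = 9500L, s_end = 9900L),
              fake_hit(query_id = "d", s_start = 3000L, s_end = 3600L))
  expect_equal(coding_overlap(pl, ann), 75)
  expect_equal(coding_overlap(pl[4, , drop = FALSE], ann), 0)
  expect_equal(coding_overlap(pl[1:3, ], ann), 100)
})

test_that("collinearity blocks resolve mixed-orientation gene orders", {
  # identity mapping: one same-orientation block of five
  id5 <- data.frame(pos_a = 1:5, pos_b = 1:5)
  res <- collinearity_blocks(id5)
  expect_equal(nrow(res$blocks), 1L)
  expect_identical(res$blocks$orientation, "same")
  expect_equal(res$blocks$length, 5L)
  # (1,2,3,4,5) -> (1,2,5,4,3): {1,2} same + {3,4,5} inverted
  rearr <- data.frame(pos_a = 1:5, pos_b = c(1, 2, 5, 4, 3))
  res2 <- collinearity_blocks(rearr)
  expect_equal(nrow(res2$blocks), 2L)
  lens <- sort(res2$blocks$length)
  expect_equal(lens, c(2L, 3L))
  expect_setequal(res2$blocks$orientation, c("same", "inverted"))
  inv <- res2$members[[which(res2$blocks$orientation == "inverted")]]
  expect_setequal(rearr$pos_a[inv], 3:5)
  # empty input
  expect_equal(nrow(collinearity_blocks(id5[0, ])$blocks), 0L)
  expect_error(collinearity_blocks(data.frame(pos_a = c(1, 1),
                                              pos_b = 1:2)),
               "duplicate")
})

test_that("longest block equals the exhaustive monotone-chain oracle", {
  set.seed(63)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    pairs <- data.frame(pos_a = sample(seq_len(n + 3), n),
                        pos_b = sample(seq_len(n + 3), n))
    res <- collinearity_blocks(pairs, max_gap = 2, min_block = 1)
    longest <- if (nrow(res$blocks) == 0) 1L else max(res$blocks$length)
    expect_equal(longest, brute_longest_chain(pairs, 2))
  }
})

test_that("gene density reproduces printed arithmetic", {
  expect_equal(gene_density(439, 7.2e6), 16.4)
  expect_equal(gene_density(451, 7.2e6), 16.0)
  expect_equal(gene_density(1, 10000), 10.0)
  expect_true(is.na(gene_density(0, 1e6)))
})

test_that("seeded read mapping recovers planted positions on both strands", {
  set.seed(64)
  ref <- c(chrA = rand_dna(150000))
  r1 <- substr(ref[["chrA"]], 40001, 40700)
  r2 <- revcomp(substr(ref[["chrA"]], 90001, 90650))
  reads <- c(m1.f = r1, m1.r = r2)
  hits <- map_reads_nt(reads, ref)
  b <- best_placement(hits)
  h1 <- b[b$query_id == "m1.f", ]
  h2 <- b[b$query_id == "m1.r", ]
  expect_equal(h1$s_start, 40001L)
  expect_identical(h1$strand, "+")
  expect_identical(h2$strand, "-")
  expect_equal(min(h2$s_start, h2$s_end), 90001L)
})
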