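test_that("threshold rules: 12 nt for periods 1-3, 4 units for 4-6", {
  expect_equal(nrow(find_ssrs(c(x = "ATATATATATAT"))), 1L)   # exactly 12
  hit <- find_ssrs(c(x = "ATATATATATAT"))
  expect_identical(hit$motif, "AT")
  expect_equal(hit$period, 2L)
  expect_equal(hit$length, 12L)
  expect_equal(nrow(find_ssrs(c(x = "ATATATATAT"))), 0L)     # 10 nt
  tetra <- find_ssrs(c(x = "ACGTACGTACGTACGT"))
  expect_equal(tetra$motif, "ACGT")
  expect_equal(tetra$unit_count, 4)
  expect_equal(nrow(find_ssrs(c(x = "ACGTACGTACGT"))), 0L)   # 3 units
  expect_equal(nrow(find_ssrs(c(x = ""))), 0L)
  # N breaks runs
  expect_equal(nrow(find_ssrs(c(x = "AAAAAANAAAAAA"))), 0L)
})

test_that("fractional trailing units count toward length", {
  hit <- find_ssrs(c(x = "GATGATGATGATGA"))  # 4 units + 2 nt
  expect_equal(hit$length, 14L)
  expect_equal(hit$unit_count, 14 / 3)
})

test_that("planted SSRs in a random background are recovered exactly", {
  set.seed(202)
  plant <- data.frame(
    motif = c("A", "AG", "GCC", "AAG", "ACGT", "AACGT", "ACGCTG"),
    units = c(14L, 8L, 6L, 5L, 5L, 4L, 4L))
  seq <- rand_dna(10000)
  # verify the background itself is clean at this seed, then plant at
  # spaced offsets with run-breaking flanks
  stopifnot(nrow(find_ssrs(c(bg = seq))) == 0)
  pos <- seq(200, by = 400, length.out = nrow(plant) * 3)
  truth <- list()
  k <- 0
  for (rep in 1:3) for (i in seq_len(nrow(plant))) {
    k <- k + 1
    run <- strrep(plant$motif[i], plant$units[i])
    substr(seq, pos[k], pos[k] + nchar(run) - 1) <- run
    truth[[k]] <- data.frame(start = pos[k],
                             end = pos[k] + nchar(run) - 1,
                             motif = plant$motif[i])
  }
  truth <- do.call(rbind, truth)
  found <- find_ssrs(c(x = seq))
  oracle <- brute_ssrs(seq)
  expect_equal(found[, c("start", "end", "period", "motif")], oracle,
               ignore_attr = TRUE)
  # every planted locus is present with matching motif and coordinates
  for (i in seq_len(nrow(truth))) {
    m <- found[found$start <= truth$start[i] & found$end >= truth$end[i], ]
    expect_gte(nrow(m), 1)
  }
})

test_that("scanner agrees with the brute-force oracle on random strings", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(50:800, 1)
    # low-cardinality alphabets provoke dense, overlapping repeats
    letters_n <- sample(2:4, 1)
    s <- paste(sample(c("A", "C", "G", "T")[1:letters_n], n, TRUE),
               collapse = "")
    if (runif(1) < 0.3)  # inject Ns
      s <- paste0(substr(s, 1, n %/% 2), "N", substr(s, n %/% 2 + 1, n))
    got <- find_ssrs(c(x = s))[, c("start", "end", "period", "motif")]
    exp <- brute_ssrs(s)
    expect_equal(got, exp, ignore_attr = TRUE)
  }
})

test_that("loci are maximal and motifs primitive", {
  set.seed(13)
  n_checked <- 0L
  for (i in 1:50) {
    # two-letter alphabet makes tandem runs dense
    s <- paste(sample(c("A", "T"), 600, TRUE), collapse = "")
    loci <- find_ssrs(c(x = s))
    if (nrow(loci) == 0) next
    n_checked <- n_checked + nrow(loci)
    ch <- strsplit(s, "")[[1]]
    for (j in seq_len(nrow(loci))) {
      p <- loci$period[j]; st <- loci$start[j]; en <- loci$end[j]
      # interior periodicity
      expect_true(all(ch[(st + p):en] == ch[st:(en - p)]))
      # non-extensible at both ends
      if (st > 1) expect_false(isTRUE(ch[st - 1] == ch[st - 1 + p]))
      if (en < length(ch)) expect_false(isTRUE(ch[en + 1] == ch[en + 1 - p]))
      # primitive motif
      m <- loci$motif[j]
      if (p > 1) for (d in seq_len(p - 1)) {
        if (p %% d == 0)
          expect_false(m == strrep(substr(m, 1, d), p / d))
      }
    }
  }
  expect_gt(n_checked, 20)
})

test_that("reverse complement mirrors loci and preserves classes", {
  set.seed(31)
  s <- paste0(rand_dna(100), strrep("GCC", 7), rand_dna(50),
              strrep("AT", 9), rand_dna(100))
  fwd <- find_ssrs(c(x = s))
  rev <- find_ssrs(c(x = revcomp(s)))
  n <- nchar(s)
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- data.frame(start = n - rev$end + 1L, end = n - rev$start + 1L)
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(mirrored$start, sort(fwd$start))
  # classes agree up to motif phase (maximal-run boundaries may shift the
  # reported rotation; tabulation keeps rotations distinct by design)
  expect_setequal(rotation_classes(fwd$motif), rotation_classes(rev$motif))
})

test_that("canonical motif classes pair a motif with its reverse complement", {
  expect_identical(canonical_motif_class("GGC"), "GCC/GGC")
  expect_identical(canonical_motif_class("CGC"), "CGC/GCG")
  expect_identical(canonical_motif_class("AT"), "AT/AT")
  expect_identical(canonical_motif_class("A"), "A/T")
  expect_error(canonical_motif_class("ATAT"), "primitive")
  expect_error(canonical_motif_class("ATATATA"), "1-6")
})

test_that("summaries report density and long-locus counts", {
  # the published corpus-level numbers are pure arithmetic on the counts
  fake <- data.frame(read_id = "x", start = 1, end = 12, period = 2,
                     motif = "AT", length = 12, unit_count = 6)
  s <- summarize_ssrs(fake[rep(1, 50206), ], 263.2e6)
  expect_equal(s$density_kb_per_ssr, 5.2)
  one <- data.frame(read_id = "x", start = 1, end = 30, period = 2,
                    motif = "AT", length = 30, unit_count = 15)
  s1 <- summarize_ssrs(one, 1000)
  expect_equal(s1$count_over_cutoff, 1L)
  s0 <- summarize_ssrs(fake[0, ], 1000)
  expect_true(is.na(s0$density_kb_per_ssr))
  expect_equal(s0$total_count, 0L)
})

test_that("planted class proportions are recovered from a synthetic corpus", {
  set.seed(404)
  mix <- c("GCC" = 30, "AG" = 15, "AT" = 10)
  reads <- character()
  truth_class <- character()
  k <- 0
  for (m in names(mix)) for (i in seq_len(mix[[m]])) {
    k <- k + 1
    units <- ceiling(12 / nchar(m)) + sample(0:3, 1)
    reads[paste0("r", k)] <-
      paste0(rand_dna(150), strrep(m, units), rand_dna(150))
    truth_class[k] <- canonical_motif_class(m)
  }
  loci <- find_ssrs(reads)
  got <- table(rotation_classes(loci$motif))
  for (m in names(mix)) {
    cls <- rotation_classes(m)
    # small slack: background SSRs are rare but not impossible
    expect_lte(abs(got[[cls]] - mix[[m]]), 3)
  }
})
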