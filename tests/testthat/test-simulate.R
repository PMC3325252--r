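small_cfg <- function(seed = 17, ...) {
  args <- list(
    seed = seed, genome_length = 3e5, clone_count = 120L,
    gene_count = 8L,
    repeat_families = data.frame(
      name = c("Gypsy1", "EnSpm1"),
      class_path = c("Retroelements/LTR/Ty3-Gypsy",
                     "DNATransposon/En-Spm"),
      length = c(600L, 400L), copies = c(20L, 12L),
      divergence = c(0.05, 0.05), stringsAsFactors = FALSE),
    ssr_spec = data.frame(motif = c("AG", "GCC"), count = c(10L, 10L),
                          min_units = c(8L, 5L), max_units = c(12L, 8L)),
    inversions = data.frame(n = 1, min_size = 4e4, max_size = 6e4),
    translocations = data.frame(n = 1, min_size = 3e4, max_size = 4e4))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

test_that("simulation is byte-identical under the same seed", {
  cfg <- small_cfg()
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1, s2)
  b1 <- simulate_bes(s1, cfg)
  b2 <- simulate_bes(s2, cfg)
  expect_identical(b1, b2)
  r1 <- simulate_related_reference(s1, cfg)
  r2 <- simulate_related_reference(s2, cfg)
  expect_identical(r1, r2)
  # a different seed changes the output
  s3 <- simulate_genome(small_cfg(seed = 18))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("every truth interval slices back to the planted sequence", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  g <- sim$genome[[1]]
  tr <- sim$truth$repeats
  for (i in seq_len(nrow(tr)))
    expect_identical(substr(g, tr$start[i], tr$end[i]), tr$planted_seq[i])
  ts <- sim$truth$ssrs
  for (i in seq_len(nrow(ts)))
    expect_identical(substr(g, ts$start[i], ts$end[i]),
                     strrep(ts$motif[i], ts$units[i]))
  tg <- sim$truth$genes
  for (i in seq_len(nrow(tg))) {
    cds <- substr(g, tg$start[i], tg$end[i])
    if (tg$strand[i] == "-") cds <- revcomp(cds)
    aa <- bessurvey:::translate_nt(cds)
    expect_identical(substr(aa, 1, nchar(aa) - 1), tg$peptide[i])
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
  }
})

test_that("an empty config yields pure background", {
  cfg <- sim_config(seed = 3, genome_length = 5e4,
                    repeat_families = default_repeat_families()[0, ],
                    ssr_spec = default_ssr_spec()[0, ], gene_count = 0L)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth$repeats), 0L)
  expect_equal(nrow(sim$truth$ssrs), 0L)
  expect_equal(nrow(sim$truth$genes), 0L)
  expect_equal(nchar(sim$genome[[1]]), 5e4)
})

test_that("planted divergence is realized within binomial error", {
  cfg <- small_cfg(seed = 19)
  sim <- simulate_genome(cfg)
  tr <- sim$truth$repeats[sim$truth$repeats$family == "Gypsy1", ]
  cons <- sim$families[["Gypsy1"]]
  ident <- vapply(seq_len(nrow(tr)), function(i) {
    copy <- if (tr$strand[i] == "+") tr$planted_seq[i] else
      revcomp(tr$planted_seq[i])
    a <- strsplit(copy, "")[[1]]
    b <- strsplit(cons, "")[[1]]
    mean(a == b)
  }, numeric(1))
  # divergence 0.05 over 600 bp and 20 copies: mean within 3 se
  se <- sqrt(0.05 * 0.95 / (600 * 20))
  expect_lt(abs(mean(1 - ident) - 0.05), 3 * se + 1e-3)
})

test_that("clone and read models behave as configured", {
  cfg <- small_cfg(seed = 23, clone_count = 400,
                   contaminant_fraction = 0.1)
  sim <- simulate_genome(cfg)
  bes <- simulate_bes(sim, cfg)
  expect_equal(length(bes$reads), 2 * 400)
  expect_equal(nrow(bes$clones), 400)
  # error rate 0 and long read: prefix equals the genomic substring
  cfg0 <- small_cfg(seed = 23, clone_count = 10)
  cfg0$error_rate <- 0
  bes0 <- simulate_bes(sim, cfg0)
  cl <- bes0$clones[!bes0$clones$contaminant, ][1, ]
  fwd <- bes0$reads[[paste0(cl$clone_id, ".f")]]
  expect_identical(fwd, substr(sim$genome[[1]], cl$start,
                               cl$start + nchar(fwd) - 1L))
  rev <- bes0$reads[[paste0(cl$clone_id, ".r")]]
  expect_identical(revcomp(rev),
                   substr(sim$genome[[1]], cl$end - nchar(rev) + 1L,
                          cl$end))
  # contaminant fraction within 3 binomial standard errors
  obs <- mean(bes$clones$contaminant)
  expect_lt(abs(obs - 0.1), 3 * sqrt(0.1 * 0.9 / 400))
  # insert mean recovered within 2 se
  ins <- bes$clones$insert_len[!bes$clones$contaminant]
  expect_lt(abs(mean(ins) - cfg$insert_mean), 2 * sd(ins) / sqrt(length(ins)))
  # read lengths respect the bounds
  expect_true(all(nchar(bes$reads) <= cfg$read_max))
})

test_that("zero rearrangements give an identical reference", {
  cfg <- small_cfg(seed = 29,
                   inversions = data.frame(n = 0, min_size = 0,
                                           max_size = 0),
                   translocations = data.frame(n = 0, min_size = 0,
                                               max_size = 0))
  sim <- simulate_genome(cfg)
  rel <- simulate_related_reference(sim, cfg)
  expect_identical(unname(rel$reference["chrA"]), sim$genome[[1]])
  expect_equal(nrow(rel$orthology), nrow(sim$truth$genes))
  expect_identical(rel$orthology$ref_start, rel$orthology$src_start)
  expect_identical(rel$orthology$pos_a, rel$orthology$pos_b)
  expect_equal(length(rel$breakpoints), 0L)
})

test_that("rearrangements flip, move and conserve gene sequences", {
  cfg <- small_cfg(seed = 31)
  sim <- simulate_genome(cfg)
  rel <- simulate_related_reference(sim, cfg)
  led <- rel$ledger
  expect_true(any(led$op == "inversion"))
  expect_true(any(led$op == "translocation"))
  expect_true("chrB" %in% names(rel$reference))
  # total sequence conserved (no deletions configured)
  expect_equal(sum(nchar(rel$reference)), nchar(sim$genome[[1]]))
  orth <- rel$orthology
  g <- sim$genome[[1]]
  for (i in seq_len(nrow(orth))) {
    src <- substr(g, orth$src_start[i], orth$src_end[i])
    tgt <- substr(rel$reference[[orth$ref_seq[i]]], orth$ref_start[i],
                  orth$ref_end[i])
    flipped <- orth$src_strand[i] != orth$ref_strand[i]
    expect_identical(if (flipped) revcomp(tgt) else tgt, src)
  }
  # genes inside an inversion are strand-flipped and order-reversed
  inv <- led[led$op == "inversion", ][1, ]
  inside <- orth[orth$src_start >= inv$src_start &
                   orth$src_end <= inv$src_end, ]
  if (nrow(inside) >= 1) {
    expect_true(all(inside$src_strand != inside$ref_strand))
    if (nrow(inside) >= 2) {
      o_src <- order(inside$src_start)
      o_tgt <- order(inside$ref_start)
      expect_identical(o_tgt, base::rev(o_src))
    }
  }
})
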