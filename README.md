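# bessurvey

Genome-wide structural surveys from BAC-end sequences (BES), in R.

Before a large, repeat-rich plant genome is assembled, a pair of BAC
libraries and a few hundred thousand Sanger end reads already answer many
questions about it: how well the libraries cover the genome, how much of
the sequence is microsatellite or transposable element, which repeat
families are novel, how GC-rich the coding fraction is, and how much
local gene order is conserved against sequenced relatives.  `bessurvey`
implements that survey as a set of composable, tested stages:

* **Library statistics** — Clarke–Carbon coverage mathematics
  (`N = ln(1-P)/ln(1-I/GS)`), genome equivalents, organellar
  contamination from hybridization screens, insert sizing from digests.
* **SSR detection** — maximal perfect tandem repeats with primitive
  period 1–6 (periods 1–3 at ≥ 12 nt, periods 4–6 at ≥ 4 units), motif
  classes paired with their reverse complements, density summaries.
* **Repeat annotation** — seeded local alignment against a class-labeled
  repeat library (RepeatMasker-style `name#class/subclass` headers),
  fragment merging so an element split by an insertion is counted once,
  soft/hard masking, low-complexity detection, hierarchical census
  tables with their headline ratios.
* **Novel repeat (SRE) mining** — all-vs-all self-comparison of masked
  reads (100 bp window at ≥ 90% identity, E ≤ 1e-50), support
  thresholding (≥ 6 matching reads), consensus building by single-linkage
  clustering and medoid star alignment, known-database filtering, and
  genome copy-number extrapolation.
* **GC / coding partition** — protein-signature intervals from six-frame
  translated alignment split each read into coding and non-coding
  fractions with separate GC estimates; GO tables are tabulated
  per namespace.
* **Comparative mapping** — hit filtering (identity ≥ 75%, E < 1e-20,
  read coverage > 50%), deterministic best placement, paired-end calling
  within a 500 kb insert bound, mate rescue inside a genomic window, and
  collinearity block detection (longest monotone chains, inversions
  included) on ortholog lists.
* **Simulator** — deterministic genomes with planted repeat families,
  SSRs, GC-rich genes and organellar contaminants; BAC clones with
  inward-facing end reads (truncated-normal lengths, mean 761 bp); and a
  rearranged related reference with a lifted annotation, orthology table
  and breakpoint ledger, so every stage is testable against known truth.

Alignment kernels (affine-gap Smith–Waterman with traceback, k-mer
seeding, SSR scanning, entropy windows) are implemented in C++ via Rcpp;
scores carry Karlin–Altschul bit scores and E-values.

## Worked example

Coverage of two libraries of 101,376 clones each (144 kb and 110 kb mean
inserts) against a 1600 Mbp genome, discounting ~1% empty clones and the
organellar fractions estimated from filter hybridization (209/36,864 and
62/36,864 chloroplast positives; 79 and 23 mitochondrial):

```r
library(bessurvey)

contamination_rate(c(209, 62, 79, 23), 36864)
#> [1] 0.57 0.17 0.21 0.06

round(genome_equivalents(101376, 144e3, 0.01, 0.0078, 1.6e9), 2)
#> [1] 8.96          # ~9 genome equivalents
round(genome_equivalents(101376, 110e3, 0.01, 0.0023, 1.6e9), 2)
#> [1] 6.88          # ~7

100 * p_find(c(101376, 101376), c(144e3, 110e3), 1.6e9)
#> [1] 99.99999      # a given locus is virtually certain to be present
```

A self-contained simulated survey:

```r
cfg <- sim_config(seed = 1, genome_length = 2e5, clone_count = 80,
                  gene_count = 4,
                  repeat_families = data.frame(
                    name = "Gypsy1",
                    class_path = "Retroelements/LTR/Ty3-Gypsy",
                    length = 500L, copies = 15L, divergence = 0.05),
                  ssr_spec = data.frame(motif = c("AG", "GCC"),
                                        count = c(8L, 8L),
                                        min_units = c(8L, 5L),
                                        max_units = c(12L, 8L)),
                  insert_mean = 30000, insert_sd = 5000,
                  insert_min = 15000, insert_max = 50000)
sim <- simulate_genome(cfg)
bes <- simulate_bes(sim, cfg)

loci <- find_ssrs(bes$reads)
summ <- summarize_ssrs(loci, sum(nchar(bes$reads)))
summ$total_count
#> [1] 9             # planted SSRs recovered from the sampled reads
summ$density_kb_per_ssr
#> [1] 13.5          # one SSR per 13.5 kb of read sequence
head(summ$by_class, 3)
#> GCC/GGC   AG/CT CCG/CGG
#>       5       3       1
```

(The 160 simulated reads cover ~122 kb, about 61% of the 200 kb toy
genome, so roughly that fraction of the 16 planted SSR loci lands in the
sample.)  `run_survey()` chains the stages and writes per-stage tables, a
plain-text report and a JSON manifest; see `?run_survey`.

## Package layout

* `R/` — one file per stage (`core_io`, `library_stats`, `ssr`, `align`,
  `repeats`, `sre`, `mapping`, `coding_gc`, `simulate`, `pipeline`).
* `src/` — Rcpp kernels (alignment, k-mer seeding, SSR scan, entropy).
* `vignettes/bes-survey-methods.Rmd` — models, parameter choices,
  simulator scope and known limitations.
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles built in code.
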