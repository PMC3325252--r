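---
title: "Methods: surveying a genome from BAC-end sequences"
author: "bessurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying a genome from BAC-end sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the models and procedures behind each stage of
the package, the tunable parameters and their defaults, the design
choices made where the design was genuinely open, and what the bundled
simulator does and does not emulate.  Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The setting

A BAC (bacterial artificial chromosome) library stores a genome as
~100–300 kb inserts; sequencing both ends of each clone yields paired
Sanger reads ("BES") of a few hundred bp that sample the genome
approximately uniformly.  A few hundred thousand BES covering 10–20% of
a genome support surprisingly complete structural inference — coverage
statistics, repeat and SSR content, GC structure, and comparative
anchoring — long before an assembly exists.  Every stage below consumes
plain FASTA/GFF3/tabular inputs and is exercised end-to-end on the
package's own simulator.

## Library coverage (Clarke–Carbon)

For a library of $N$ clones of insert size $I$ against a haploid genome
of size $GS$, the probability that a given single-copy locus is present
is $P = 1 - (1 - I/GS)^N$; inverting gives the clone count needed for a
target probability, $N = \ln(1-P)/\ln(1 - I/GS)$.  Multiple libraries
combine by multiplying miss probabilities.  `genome_equivalents()`
discounts empty and organellar-contaminant clone fractions before
dividing total effective insert length by $GS$.  Organellar
contamination is estimated directly as positives/screened from
hybridization screens, reported with half-up rounding at two decimals
(the convention that reproduces the published screen percentages
exactly).  Where a published census table disagrees with the
positives/screened arithmetic its own text reports, the package follows
the counts: they are reproducible arithmetic, the table entry is not.

Numerical care: `p_find()` uses `log1p`/`expm1`, so it is accurate for
$I/GS \sim 10^{-5}$ and very large $N$; `clarke_carbon_clones()` takes a
ceiling with a $10^{-9}$ guard so a value that is an integer up to
floating-point noise is not bumped to the next clone.

## SSR detection

An SSR locus is a maximal perfect tandem run with a primitive motif
(not itself a repetition of a shorter string) of period 1–6.  Period
classes 1–3 must reach **12 nt total length**; classes 4–6 must reach
**4 units**; a fractional trailing unit counts toward the length.  `N`
breaks runs; identical intervals are reported once under the smallest
period; the motif is reported in its first-occurring phase, and
tabulation groups a motif only with its reverse complement (rotations
stay distinct), so GCC/GGC and CGC/GCG are separate classes.

Only perfect repeats are detected.  Mismatch-tolerant detection would
require a resolution parameter with no principled default, and perfect
runs make the scanner exactly checkable: the suite compares it against a
brute-force enumerator on a thousand random sequences, including
low-cardinality alphabets that provoke dense overlapping runs.

SSR density is reported as (total corpus bases / 1000) / locus count —
the denominator includes masked and N bases, so the statistic is a
property of the whole corpus surveyed.

## The alignment engine

All homology stages share one affine-gap local aligner (Rcpp).  A gap of
length $L$ scores `gap_open + L * gap_extend` (defaults $-5, -2$;
nucleotide match/mismatch $+1/-2$).  Scores are converted to bit scores
$S' = (\lambda S - \ln K)/\ln 2$ and E-values $E = Kmn\,e^{-\lambda S}$
with the standard ungapped blastn constants $\lambda = 1.28$, $K = 0.46$
as a documented approximation; protein mode uses BLOSUM62 with gap
$-11/-1$ and $\lambda = 0.267$, $K = 0.041$.  E-values are therefore
comparable across runs but are not NCBI-exact, which is why every
threshold in the pipeline is an explicit parameter.

Strategy: below ~4 million DP cells the aligner runs the exact full
Smith–Waterman, so for read-scale pairs the reported optimum *is* the
optimum.  For long subjects, exact k-mer seeds (default 12) vote for a
diagonal, and the DP runs on a padded window around it; the heuristic
can only under-report, never exceed, the true optimum.  Additional hits
between one pair — an element fragmented by a long insertion — are
recovered by masking the accepted query span and re-aligning.  The test
suite checks exact score agreement against an independent
Smith–Waterman implementation (`Biostrings::pairwiseAlignment`) in both
nucleotide and protein modes.

Translated alignment enumerates all six frames under the standard code;
stops split a frame into segments that are aligned independently, so a
stop never sits inside an alignment, and hit coordinates are mapped back
to nucleotide space with the frame recorded.

## Known-repeat annotation

Reads are searched against both strands of every library element
(RepeatMasker-style `name#class/subclass` FASTA headers), with a k-mer
prefilter so only read/element pairs sharing seeds are aligned.
Fragments of the same element on the same read, in consistent order and
orientation, separated by at most 100 bp on the read and 500 bp on the
element, merge into one counted element — the counting principle that an
element fragmented by later insertions represents a single insertion
event.  The gap defaults reflect nested-insertion scale at read length;
both are parameters.  Masking is soft (lowercase) by default so
downstream stages can ignore repeat bases without losing them; hard
masking substitutes N.  Census tables aggregate hierarchical classes on
per-read interval unions (no double counting within a class), and
`repeat_summary_ratios()` derives the headline shares (class I vs II,
LTR share, En-Spm share, Gypsy:Copia) from any such table, including a
published census transcribed as input.

Low-complexity sequence is flagged by trinucleotide Shannon entropy in
64 bp windows (step 32) below 1.4 bits: homopolymers score 0 bits and
dimer runs 1 bit, while random uniform sequence sits near 5.5 bits, so
the threshold separates the regimes by a wide margin.  SSR and
low-complexity intervals may overlap the same bases by design — they are
reported in separate census sections, and only transposon classes count
toward the interspersed-repeat total.

## Novel repeat (SRE) mining

Reads masked for known repeats are compared all-vs-all.  A pair counts
as a match iff some local alignment contains **≥ 100 alignment columns
at ≥ 90% identity** and passes **E ≤ 1e-50**; a read's support is its
number of distinct partners, and reads with **≥ 6** matches are carried
forward.  Candidate-pair enumeration uses canonical (strand-symmetric)
16-mers shared at least 4 times — canonicalization matters because
dispersed copies sit on both strands.

Consensus building replaces a motif-EM step with a deterministic,
oracle-testable procedure.  Two refinements proved necessary on the
planted-truth benchmark, both addressing chimerism rather than
sensitivity:

* **Multi-witness segment cores.**  A read's candidate segments are the
  maximal runs covered by ≥ 2 of its match intervals.  Clones that
  merely overlap on the genome align end-to-end and would otherwise
  contribute long unique-sequence segments; requiring two independent
  witnesses trims them and sharpens element boundaries.  Match intervals
  longer than `max_len + 100` are excluded outright for the same reason.
* **Coverage-gated single linkage.**  Segments cluster by single linkage
  at ≥ 80% identity over ≥ 80 bp, *and* the linking alignment must cover
  ≥ 80% of the shorter segment.  Without the coverage gate, a segment
  straddling two elements planted next to each other on the genome
  links both families into one cluster; single linkage then cascades
  into mega-clusters.

Each cluster is collapsed by a star alignment to its medoid (highest
total similarity; ties broken by lexicographically smallest segment id
for determinism), majority vote per medoid column, and trimming of
columns covered by fewer than half the members.  Consensi outside
80–300 bp or supported by fewer than 6 distinct reads are discarded.
Candidates with any nucleotide or translated hit at E ≤ 1e-4 against the
supplied known databases are removed; survivors get a genome copy
estimate `floor(support / sampled_fraction)`, where the sampled fraction
defaults to total read bases over genome size.

## GC and coding partition

A "protein signature" is operationalized as a passing translated-
homology interval; HMM domain search is out of scope, so GO annotations
enter as a read→term table and are tabulated per namespace.  GC is
computed over A/C/G/T only (N excluded from the denominator), and the
partition satisfies the length-weighted identity
`overall = (coding_gc·coding_bases + noncoding_gc·noncoding_bases) /
total` to within rounding — the same identity used to check published
GC triples for internal consistency.

## Comparative mapping and collinearity

Placement applies three filters jointly — identity ≥ 75%, E < 1e-20
(strict), read coverage > 50% (strict, over the full read length
including masked bases; the denominator choice is a documented
convention) — then picks the best placement per read by bit score with
deterministic tie-breaks (E-value, subject id, leftmost coordinate).
Clones whose ends place on one reference sequence with an outermost span
≤ 500 kb become paired placements (microsyntenous regions); everything
else placed is a high-scoring singlet.  Orientation is recorded but not
enforced by default, matching the span-only published rule; the optional
strict mode requires convergent ends and is what the rearrangement
benchmark uses, since an inversion flips one end's strand while its span
can stay under the bound.  An unplaced mate of a coding-placed end can
be rescued by nucleotide alignment inside a ± max-insert window, with
identity and coverage bounds but no E constraint (the search space is
the window, not the genome).

Collinearity blocks chain ortholog pairs monotone in both genomes
(increasing = same orientation, decreasing = inversion), allowing up to
2 skipped genes per side per step.  Blocks are extracted greedily —
longest chain first, ties broken by fewest skipped genes, same before
inverted, then leftmost — removing used pairs and repeating; leftovers
are reported as rearranged.  The chain finder is verified against an
exhaustive subset oracle for lists up to 12 genes.

## The simulator

`sim_config()` defaults describe the package's scaled test bed: a 2 Mbp
genome at 45% GC; five named repeat families spanning the major
transposon classes; an SSR spectrum that is trimer-dominant and GC-rich
(echoing grass genomes; ~360 loci ≈ one per 5.6 kb); GC-biased genes
produced by back-translating random peptides with G/C-ending codon
preference; 1,500 clones with truncated-normal inserts (40 ± 8 kb,
bounds 20–80 kb — inserts are scaled to the toy genome, not to real BAC
inserts); inward-facing end reads with truncated-normal lengths
(761 ± 120 bp, bounds 100–1000) and 1% substitution error; and 0.5%
organellar-contaminant clones drawn from a simulated 120 kb organellar
sequence.  The related reference applies non-overlapping inversions,
translocations (moved to a second chromosome) and deletions drawn as
blocks; genes are lifted through the block map, genes spanning a
breakpoint are dropped from the orthology, and every operation is
recorded.

Truth tables are complete: slicing any truth interval out of the emitted
sequence reproduces the planted (mutated) copy exactly, and everything
is byte-deterministic under the seed.

What the simulator does **not** emulate: chromatograms and quality
values, indel sequencing error, polyploidy and homoeologous
subgenomes, nested or truncated transposon insertions, imperfect or
compound SSRs, and realistic organellar sequence (it is random DNA at
38% GC).  Tests passing on this bed therefore demonstrate algorithmic
correctness against known truth, not performance on real Sanger data.

## Benchmark problem sizes

The acceptance-style suites run, at fixed seeds: the SSR scanner against
a brute-force oracle on 1,000 random sequences up to 2 kb; the aligner
against an independent Smith–Waterman on 500 random pairs up to 200 bp
and BLOSUM62 protein cases; SRE mining on a 2 Mbp genome with 20
discoverable families (150–250 bp, 35–60 copies, 2.5% divergence, ~19%
of the genome), a 5-copy control family that must stay undetected, and
two masked known families, sampled by 430 clones (~33% of the genome) so
typical families have tens of supporting reads; and pairing on a 2 Mbp
genome with one 250–350 kb inversion and one 150–250 kb translocation
sampled by 150 clones.  These sizes keep the full suite in the
low minutes on one CPU while leaving each check statistically
informative.

## Known limitations

* E-values are Karlin–Altschul approximations with fixed constants;
  rely on them for ranking and thresholding, not for cross-tool
  comparison.  Discontiguous (spaced) seeds are not implemented; very
  diverged homology is better supplied as precomputed tabular hits.
* The seeded path examines the single best diagonal bin per
  subject/strand, so a query repeated at several loci of one long
  subject yields only the best locus unless searched via the repeat
  annotator (which iterates per element) or supplied pre-seeded.
* Single linkage, even coverage-gated, can merge families that share
  genuine sequence (e.g. solo-LTR-like relationships); the catalog
  reports support and members so such cases can be audited.
* The GFF3 writer rejects attribute values containing reserved
  characters rather than escaping them.
* `run_survey()` executes stages sequentially on one CPU; the survey
  scale this package targets (10^5 reads) keeps that practical, but
  whole-genome corpora would need chunked or delegated alignment.
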