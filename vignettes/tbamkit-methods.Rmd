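---
title: "Methods behind tbamkit: targeted multiplexed bacterial RNA-seq"
author: "tbamkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind tbamkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models and procedures implemented in
`tbamkit`, the parameters that matter, the choices made where the design
was genuinely open, and what the simulation-based tests do and do not
establish about real data.

## The experimental setting

In the multiplexed workflow the package supports, fragmented bacterial
RNA is dephosphorylated, polyadenylated in vitro, and reverse-transcribed
with barcoded oligo(dT) primers, after which all samples are pooled and
processed together. The targeted variant enriches the pooled cDNA for
chosen transcripts through one cycle of second-strand synthesis primed by
gene-specific oligos that carry a common 5' adapter; PCR from that
adapter then retains only targeted molecules. Computationally this
implies five tasks: designing the second-strand primer panel, trimming
the poly(A) tails off reads, mapping and 5'-adjusting them, quantifying
at gene or primer resolution, and estimating the two artifacts that
pooling introduces — barcode switching between samples and nonspecific
(misprimed) second-strand synthesis.

## Primer panel design

Primers are forward primers on the coding strand: the second strand is
synthesised 5'→3' along the transcript, so a primer's sequence equals the
genomic sequence of its annealing window on the gene's sense strand.

Candidates are every window of length 18–22 nt inside the gene whose
melting temperature falls in [53, 56] °C. Each candidate gets the penalty

    |Tm - 55| + 0.5 * |len - 20|

so that 20-mers melting at 55 °C are preferred. The paper-style toolchain
delegates candidate generation to an external primer-design program; this
package instead enumerates windows exhaustively with an internal Tm
model, because the binding constraints (size window, Tm window, rRNA
filter, spacing) are what actually determine the pool, and an exhaustive
deterministic generator is testable against a brute-force oracle.

**Melting temperature.** A nearest-neighbor thermodynamic sum over the
ten Watson–Crick dinucleotide stacks (the unified parameter set of
SantaLucia's 1998 compilation), plus terminal initiation terms that
distinguish G·C from A·T ends, with the entropic salt correction
`0.368 (N−1) ln[Na+]`. Conditions are fixed and documented: 50 mM
monovalent cation, 250 nM total oligo, `CT/4` in the melting equation
(`CT/1` for self-complementary oligos). These are conventional
primer-design conditions; both are arguments of
`melting_temperature()`, never silent state.

**rRNA homology filter.** Because rRNA dominates total RNA, a primer
sharing even a short exact word with an rRNA region misprimes massively.
A candidate is removed when any of its 8-mers occurs exactly in any rRNA
region *or its reverse complement*. Searching both strands is our
documented choice: the filter emulates aligning all primer 8-mers to the
rRNA operons with a read aligner at zero mismatches, and read aligners
search both strands by default.

**Spacing.** Selected primers within a gene must leave at least 20 nt
between one primer's 3' end and the next primer's 5' end along the
transcript. The selection rule the constraint comes with does not specify
a search, so we use a deterministic greedy scan in transcript 5'→3'
order: walk the candidate positions; at the first position satisfying
the spacing constraint relative to the last admitted primer, admit the
lowest-penalty candidate at that position (ties: lexicographically
smallest sequence). This yields a *maximal* set — no rejected candidate
can be re-inserted anywhere without violating spacing — which the test
suite verifies directly, and it is reproducible byte-for-byte.

**Adapter.** The common adapter `CTTTCCCTACACGACGCTCTTCCGATCT` is
prepended to every selected primer to give the synthesis oligo; an
independent validator (`validate_primer_pool()`) rechecks every pool
invariant from raw sequence and coordinates rather than trusting the
pipeline.

## Preprocessing

**Poly(A) trimming.** Reads are trimmed with 3'-adapter semantics
against a 20-A adapter: the best adapter occurrence (full internal match,
or a partial match overlapping the read's 3' end by ≥ 10 nt) with at most
`floor(0.1 × matched length)` errors is found, and the read is cut from
the match start. Among qualifying placements the fewest errors win, then
the longest match, then the leftmost start. Reimplementing this rather
than shelling out keeps the stage deterministic and testable against an
exhaustive placement oracle; the conventional options (error rate 0.1,
min overlap 10) are the defaults.

**Mapping.** The internal mapper reproduces best-stratum single-report
semantics: every end-to-end placement on both strands with ≤ 2 mismatches
is considered, exactly one alignment from the lowest-mismatch stratum is
reported, and ties break deterministically by (contig id, coordinate,
forward before reverse). Aligner tie order is generally unspecified, so
ours is fixed and documented. `N` never matches anything, including
another `N`. The inner scan is compiled (Rcpp) with an exact-match hash
fast path for the common case; the mapper is intended for fixture-scale
genomes (up to a few megabases), and external SAM/bowtie-legacy files are
the ingestion path for real-scale data. Mismatch counting ignores base
quality, matching quality-blind alignment modes.

**5' adjustment.** Gene counting and primer matching use a read's 5'
position in a single convention: forward reads keep their mapped
position, reverse reads use `pos + read_length` (one past the 5' base).
External 1-based SAM positions are converted to the internal 0-based
convention first and adjusted afterwards; the order matters only by one
base, and fixing it removes the ambiguity.

## Quantification

**Gene counting** uses only each read's adjusted 5' position and
requires strand agreement; positions within the first or last 30 nt of
the CDS (transcript orientation) are excluded, avoiding edge pile-ups.
Reads whose 5' position falls in the countable window of more than one
gene are dropped and logged (deterministic, conservative). Genes shorter
than 60 nt have a zero countable window and warn.

**rpm.** Reads per million use the sample's total feature-assigned reads
as denominator — this makes rpm sum to 10^6 per sample and is our
documented reading, since the normalisation base for gene-level rpm is
otherwise ambiguous. The reporting threshold is *strictly more than* 100
reads; counts below it are retained internally but reported as `NA`.
Zero-denominator samples are flagged, never silently zeroed.

**Primer assignment** matches a read's adjusted 5' position to primer
annealing coordinates on the matching strand. The default tolerance is
0 nt — the strictest reading of "matching location", and the simulator
produces exact positions — with an argument to relax it. The nearest
primer wins; exactly equidistant reads stay unassigned and are flagged.
Per-primer rpm uses total primer-assigned reads as denominator, and a
gene covered by several primers is summarised by the *median* primer rpm
(even counts: mean of the middle two), which damps per-primer efficiency
outliers.

**Mispriming classification.** Reads that fail end-to-end mapping are
split at 20 nt; head and tail are remapped independently. A head mapping
at a primer annealing coordinate marks a nonspecific second-strand event;
the off-target body location comes from the tail's mapping (unresolved if
the tail is < 15 nt or unmappable). One refinement: a candidate whose
tail maps contiguously downstream of its own head (within 2 nt, same
contig and strand) is discarded, because such a read is an ordinary
specific read that merely failed end-to-end mapping — typically through a
3–9 nt poly(A) stub too short to trim. Only *resolved* events are
evidence of chimerism; rate estimates in the test suite therefore count
resolved events over all reads.

**Agreement statistics.** Pairwise Pearson correlations are computed on
log10 rpm, restricting each pair to features above the reporting
threshold in both of its samples; the replicate-noise summary is the
median across features (above threshold in every sample) of the standard
deviation of log2 rpm. The underlying phrase "median SD of log2
fold-changes" admits several readings; this one is applied uniformly and
recovers injected multiplicative noise in simulation.

## Barcode switching and depth planning

Two estimators quantify barcode switching. In a *knockout pool*, one
sample entirely lacks a gene present at wildtype level in the other
samples, so any reads of that gene under the knockout barcode must have
switched in: the per-pair rate is `(ko/wt) / n_target_samples`. In a
*mixed-species pool*, reads carrying one species' barcode but mapping to
the other species' genome give `foreign / total`. Both are scale
invariant and carry numerator/denominator provenance in the returned
object. Inputs are counts at matched depth; per-million normalisation is
an upstream responsibility when depths differ.

*Depth planning.* At reference depth, gene `i` has `c_i` reads (sorted
descending). For every gene to reach `m` reads (default 100), one pool
needs `ceil(m / c_last × sum(c))` reads. Splitting the genes into `k`
consecutive abundance tiers, enriching each tier in its own second-strand
reaction, and re-mixing lets each tier satisfy the formula locally; the
totals sum and the fold reduction is reported. Group sizes are equal up
to a remainder assigned to the earliest groups; we use exact equal blocks
(the verbal description "genes 1–199, 200–399" alongside "each containing
200 genes" is off by one, and the 200-gene reading matches the
arithmetic). Required reads are rounded up because reads are discrete.
For any descending-ordered grouping the fold reduction is ≥ 1, with
equality exactly when within-group skew matches whole-set skew; `k = n`
reaches the scheme's floor of `n × m` reads.

## The simulator

`sim_config()` fixes the study conditions; a single integer seed
determines everything, with per-stage substreams derived from it so that
adding a stage never perturbs earlier draws.

* **Reference**: one contig of uniform random DNA holding non-overlapping
  CDS genes on random strands (400–1200 nt by default) and rRNA regions
  (2 × 1200 nt), separated by 40–120 nt intergenic gaps.
* **Abundances**: log-normal, normalised. The default
  `abundance_sigma = 1.802` solves `pnorm(sigma − qnorm(0.99)) = 0.30`
  analytically, i.e. the top 1% of genes carry 30% of transcripts in
  expectation — the skew that motivates targeted enrichment in the first
  place. `sigma = 0` degenerates to uniform.
* **Reads** (multiplexed mode): gene ∝ abundance (or rRNA with
  probability `rrna_fraction`; default 0, emulating pre-depleted input),
  fragment uniform within the gene (70–120 nt, emulating gel size
  selection), poly(A) tail of 8–25 nt appended, truncated to the 50-nt
  read length. With fragments at least as long as the read, default-mode
  reads are pure genomic sequence; configurations with shorter fragments
  exercise the trimmer.
* **Targeted mode**: a pool primer is chosen ∝ its gene's abundance ×
  a per-primer efficiency (equal by default); the read runs from the
  primer's 5' end through the 3' end of a fragment containing the priming
  site, into the poly(A) tail. With probability `misprime_rate` (default
  0.1, mirroring the ~90% specific-priming levels such libraries reach)
  the read is instead a chimera: the primer sequence followed by a body
  from a uniformly random off-target locus, recorded in the truth table.
* **Barcode switching**: `switch_rate` is the *per-pair* probability that
  a read is emitted under one specific other sample's barcode (so total
  switching is `switch_rate × (n_samples − 1)`). The per-pair definition
  is deliberate: it is the quantity the knockout estimator reports, so an
  injected rate of 0.01 should be recovered as 0.01. Abundances may be
  given per sample (a matrix) to build knockout designs.

**What the simulator does not model**: sequencing errors and quality
scores, primer thermodynamic efficiency differences (efficiency is an
explicit knob, not emergent), template-switching artifacts, rRNA
depletion chemistry, paired-end reads, and real genome repeat structure.
Consequently, passing recovery tests demonstrates that the *pipeline
logic* is correct and self-consistent — not that real libraries are free
of artifacts the generator does not produce.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; conversion happens once,
  at file boundaries. The reverse-strand adjusted position is one past
  the 5' base, so gene counting uses `adj_pos − 1` for reverse reads.
* Tie-breaks are explicit everywhere: mapper (contig, coordinate,
  forward first), trimmer (errors, match length, leftmost), selection
  (penalty, then sequence), assignment (nearest; exact ties unassigned).
* Genes shorter than the minimum primer length yield empty candidate
  lists, not errors; empty rRNA sets filter nothing; empty pools error in
  targeted simulation; zero-count genes make depth planning error because
  no finite depth covers them.
* Problem sizes in the test suite were chosen as the smallest that leave
  the statistical checks well-powered: recovery runs use 6 samples ×
  10^5 reads on a ~30 kb genome with 40 genes; oracle-equivalence runs
  use 1000 reads against a 50 kb genome. Thresholds (binomial 95% CI,
  2 standard errors, Spearman ρ ≥ 0.95) follow from the injected rates
  and these sizes, and were fixed before the runs.

## Known limitations

* The internal mapper is exhaustive and meant for fixture-scale genomes;
  real datasets should arrive as external SAM/bowtie alignments.
* The Tm model is a standard nearest-neighbor approximation; oligos with
  unusual salt conditions, dangling ends or secondary structure are not
  modelled, and hairpin/dimer screening is out of scope by design.
* BED input carries no feature type, so rRNA regions in BED are
  recognised only by name (`rRNA`/`rrn` patterns); GFF3 is the richer
  and preferred dialect.
* The knockout estimator assumes matched sequencing depth between the
  knockout and wildtype samples; normalise upstream otherwise.
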