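# tbamkit

Computational toolkit for **multiplexed and targeted bacterial RNA-seq**.

Bacterial mRNAs carry no poly(A) tails, so the cheap eukaryotic trick of
barcoding samples with oligo(dT) reverse-transcription primers does not
apply directly. A practical workaround is to polyadenylate fragmented RNA
3' ends enzymatically, reverse-transcribe with barcoded oligo(dT) primers,
and pool everything early into one tube. A targeted variant then enriches
the pooled cDNA for chosen transcripts with a single second-strand
synthesis cycle, primed by ~50-nt oligos made of a 28-nt common adapter
plus a ~20-nt gene-specific sequence.

`tbamkit` implements the computational side of both workflows as a
reusable R package:

* **Primer-panel design** — exhaustive window enumeration on the coding
  strand of each target gene under length (18–22 nt, optimum 20) and
  nearest-neighbor melting-temperature (53–56 °C, optimum 55) constraints;
  removal of any candidate sharing an exact 8-mer with an rRNA region on
  either strand; greedy 5'→3' selection enforcing ≥ 20 nt from each
  selected primer's 3' end to the next primer's 5' end; and appending of
  the common adapter `CTTTCCCTACACGACGCTCTTCCGATCT`.
* **Preprocessing** — poly(A)-tail trimming with 3'-adapter semantics
  (20-A adapter, min overlap 10, error rate 0.1); a small exhaustive
  best-mismatch-stratum read mapper (compiled, deterministic tie-breaks,
  `-v 2 -k 1 --best`-style semantics) plus SAM/bowtie-legacy ingestion;
  and the reverse-strand 5' adjustment `adj_pos = pos + read_length`.
* **Quantification** — gene counting from 5' positions excluding the
  first and last 30 nt of each CDS; reads-per-million with a strict
  \>100-read reporting threshold; read-to-primer assignment by matching
  adjusted 5' positions to annealing coordinates; per-primer rpm over
  primer-mapped reads; gene expression as the **median primer rpm**;
  split-read classification of mispriming chimeras (first 20 nt at a
  priming site, remainder elsewhere); pairwise log10 Pearson correlations
  and the median SD of log2 expression across replicates.
* **Estimation & planning** — barcode-switching rates from knockout pools
  (`rate = (ko/wt)/n_target_samples`) and mixed-species pools
  (`rate = foreign/total`); and sequencing-depth redistribution: for genes
  ranked by abundance and split into abundance tiers, the reads required
  so every gene reaches ≥ 100 reads are
  `ceil(100 / count_last × sum(counts))` per tier, typically a large fold
  reduction versus one pool.
* **Simulation** — a truth-tracked generator of barcoded, poly(A)-tailed,
  optionally target-enriched reads (log-normal abundances skewed so the
  top 1% of genes carry ~30% of transcripts, per-pair barcode switching,
  primer-initiated chimeras), used throughout the test suite.

## Worked example

Design a panel on a simulated reference, generate targeted reads, and
recover primer-level expression:

```r
library(tbamkit)

cfg  <- sim_config(seed = 7, n_genes = 15, reads_per_sample = 5000,
                   n_samples = 2, misprime_rate = 0.1)
ref  <- make_reference(cfg)
ab   <- sample_abundances(cfg)
pool <- design_primer_pool(ref$genome, ref$genes)
pool
#> Primer pool 'pool1': 246 primers across 15 gene(s)
#>   adapter: CTTTCCCTACACGACGCTCTTCCGATCT
#>   Tm range: 53.0-56.0 C; lengths 18-22 nt

sim <- simulate_tbam_reads(ref, ab, pool, cfg)
res <- map_reads(trim_polya(sim$reads), ref$genome)
adj <- adjust_positions(res$alignments)
asg <- assign_to_primers(adj, pool)
pe  <- primer_expression(asg, pool)
ge  <- gene_expression_from_primers(pe, pool)

ev <- classify_misprimes(res$unmapped, ref$genome, pool)
sum(ev$resolved) / nrow(sim$reads)   # ~0.10: the injected misprime rate
```

In this run 8429 of 10000 reads mapped end-to-end and all of them matched
a primer annealing coordinate exactly; of the 1571 unmapped reads, 1011
resolved as primer-initiated chimeras — exactly the reads the simulator
recorded as misprimes — giving a recovered misprime rate of 0.101. The
Spearman correlation between true gene abundances and median-primer
expression was 0.995 across the 15 genes.

Switch-rate estimators work straight from printed read counts:

```r
knockout_switch_rate(3, 153, 14)
#> Barcode-switching estimate (knockout): 0.001401 (0.14%)
cross_species_switch_rate(157509, 11936187)
#> Barcode-switching estimate (mixed_species): 0.0132 (1.32%)
```

And depth planning from a descending expression profile:

```r
plan_redistribution(2^(9:0), n_groups = 2)
#> Redistribution plan: 10 genes in 2 group(s), >= 100 reads/gene
#>   group 1: 5 genes (counts 512..32) -> 3,100 reads
#>   group 2: 5 genes (counts 16..1) -> 3,100 reads
#>   tiered total: 6,200 reads; single pool: 102,300 reads; fold reduction: 16.5x
```

A command-line wrapper over the same functions ships in
`inst/scripts/tbamkit` (subcommands `design`, `trim`, `map`, `adjust`,
`count-genes`, `assign`, `expr`, `misprime`, `stats`, `switch-rate`,
`plan`, `simulate`, `convert`, `validate`).

## Package layout

```
R/                 implementation (design, preprocess, quantify,
                   estimators, simulator, IO)
src/               compiled mapper and trimmer inner loops (Rcpp)
tests/testthat/    unit, property and acceptance tests with independent
                   oracles
scripts/           acceptance script
inst/scripts/      command-line interface
vignettes/         methods vignette (model, parameters, design choices)
```
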