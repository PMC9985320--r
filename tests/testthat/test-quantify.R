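# Gene counting, rpm, primer assignment and expression, mispriming
# classification, and agreement statistics.

test_that("gene counting excludes the first and last 30 nt of the CDS", {
  genes <- toy_genes(list("gA", "chr1", "+", 100, 300, "CDS"))
  aln <- toy_alignments(100 + c(5L, 35L, 100L, 169L, 175L), "+")
  tab <- count_gene_reads(aln, genes)
  expect_identical(unname(tab$counts["gA", "s1"]), 3L)  # offsets 35, 100, 169

  # a read 10 nt into the CDS is excluded
  tab2 <- count_gene_reads(toy_alignments(110L, "+"), genes)
  expect_identical(unname(tab2$counts["gA", "s1"]), 0L)
})

test_that("gene counting works symmetrically on the reverse strand", {
  genes <- toy_genes(list("gB", "chr1", "-", 100, 300, "CDS"))
  # transcript offsets {5, 35, 100, 169, 175} from the 3' high-coordinate end:
  # the 5' base sits at genomic 299 - offset, and adj_pos is one past it.
  offsets <- c(5L, 35L, 100L, 169L, 175L)
  aln <- toy_alignments(300L - offsets, "-")
  tab <- count_gene_reads(aln, genes)
  expect_identical(unname(tab$counts["gB", "s1"]), 3L)
})

test_that("strand-mismatched reads and empty inputs give zero counts", {
  genes <- toy_genes(list("gA", "chr1", "+", 100, 300, "CDS"))
  expect_identical(unname(count_gene_reads(toy_alignments(200L, "-"),
                                           genes)$counts["gA", "s1"]), 0L)
  empty <- toy_alignments(integer(0), character(0))
  tab <- count_gene_reads(adjust_positions(empty), genes, samples = "s1")
  expect_true(all(tab$counts == 0L))
})

test_that("short genes warn and ambiguous overlaps are dropped", {
  genes <- toy_genes(list("tiny", "chr1", "+", 0, 50, "CDS"))
  expect_warning(count_gene_reads(toy_alignments(25L, "+"), genes),
                 "zero countable region")

  overlapping <- toy_genes(list("g1", "chr1", "+", 0, 200, "CDS"),
                           list("g2", "chr1", "+", 100, 320, "CDS"))
  expect_message(
    tab <- count_gene_reads(toy_alignments(150L, "+"), overlapping),
    "ambiguous")
  expect_true(all(tab$counts == 0L))
})

test_that("rpm normalises per sample and applies the strict >100 threshold", {
  counts <- matrix(c(2000L, 0L, 100L, 101L), ncol = 1,
                   dimnames = list(c("g1", "g2", "g3", "g4"), "s1"))
  tab <- table_from_counts(counts)
  expect_equal(unname(tab$rpm["g1", "s1"]), 2000 / 2201 * 1e6)
  expect_true(is.na(tab$rpm["g3", "s1"]))   # exactly 100 reads: excluded
  expect_false(is.na(tab$rpm["g4", "s1"]))  # strictly more than 100
  # reported rpm never exceeds the per-sample million
  expect_lte(sum(tab$rpm[, "s1"], na.rm = TRUE), 1e6)

  # one gene holding every counted read: rpm 1e6
  solo <- table_from_counts(matrix(500L, dimnames = list("g1", "s1")))
  expect_equal(unname(solo$rpm["g1", "s1"]), 1e6)
})

test_that("zero-denominator samples are flagged, not silently zeroed", {
  counts <- matrix(c(200L, 0L), ncol = 2,
                   dimnames = list("g1", c("s1", "s2")))
  expect_warning(tab <- table_from_counts(counts), "zero denominator")
  expect_true(is.na(tab$rpm["g1", "s2"]))
  expect_identical(tab$flagged_samples, "s2")
})

test_that("rpm is invariant to scaling one sample's counts", {
  set.seed(41)
  counts <- matrix(rpois(20, 500) + 101L, ncol = 2,
                   dimnames = list(sprintf("g%02d", 1:10), c("s1", "s2")))
  tab1 <- table_from_counts(counts)
  counts2 <- counts
  counts2[, 1] <- counts2[, 1] * 7L
  tab2 <- table_from_counts(counts2)
  expect_equal(tab1$rpm[, 1], tab2$rpm[, 1])
})

make_test_pool <- function(coords = c(500L, 900L), strand = "+",
                           gene = "gA") {
  primers <- data.frame(
    gene_id = gene, contig = "chr1", target_strand = strand,
    anneal_start = ifelse(strand == "+", coords, coords - 20L),
    anneal_end = ifelse(strand == "+", coords + 20L, coords),
    tx_start = seq(0L, by = 40L, length.out = length(coords)),
    length = 20L, sequence = strrep("AC", 10), tm = 55, penalty = 0,
    primer_id = sprintf("%s_p%d", gene, seq_along(coords)),
    anneal_coord = coords, oligo = NA_character_,
    stringsAsFactors = FALSE)
  structure(list(primers = primers, pool_id = "test",
                 adapter = design_params()$adapter), class = "primer_pool")
}

test_that("primer assignment matches location exactly at tolerance 0", {
  pool <- make_test_pool(c(500L, 900L))
  aln <- toy_alignments(c(500L, 700L, 901L), "+")
  asg <- assign_to_primers(aln, pool)
  expect_identical(asg$primer_id, c("gA_p1", NA, NA))
  expect_identical(asg$match_offset[1], 0L)
  # tolerance 1 admits the 1-nt-off read
  asg1 <- assign_to_primers(aln, pool, tolerance = 1L)
  expect_identical(asg1$primer_id, c("gA_p1", NA, "gA_p2"))
  expect_identical(asg1$match_offset[3], 1L)
  # conservation: one output row per input alignment
  expect_identical(nrow(asg), nrow(aln))
})

test_that("equidistant reads stay unassigned and are flagged as ties", {
  pool <- make_test_pool(c(500L, 510L))
  asg <- assign_to_primers(toy_alignments(505L, "+"), pool, tolerance = 5L)
  expect_true(is.na(asg$primer_id))
  expect_true(asg$tie)
})

test_that("primer expression reproduces direct rpm arithmetic", {
  pool <- make_test_pool(c(100L, 200L, 300L))
  aln <- toy_alignments(rep(c(100L, 200L, 300L), times = c(10, 20, 30)), "+")
  pe <- primer_expression(assign_to_primers(aln, pool), pool)
  expect_equal(unname(pe$rpm[, "s1"]),
               c(10, 20, 30) / 60 * 1e6, tolerance = 1e-12)
  expect_equal(sum(pe$rpm[, "s1"]), 1e6)
  # single primer holding all reads
  solo <- primer_expression(
    assign_to_primers(toy_alignments(rep(100L, 5), "+"), pool), pool)
  expect_equal(unname(solo$rpm["gA_p1", "s1"]), 1e6)
})

test_that("gene expression is the median primer rpm", {
  pool <- make_test_pool(c(100L, 200L, 300L))
  pe <- primer_expression(
    assign_to_primers(
      toy_alignments(rep(c(100L, 200L, 300L), times = c(1, 4, 100)), "+"),
      pool),
    pool)
  # primer rpms are proportional to {1, 4, 100}: median is the middle one
  ge <- gene_expression_from_primers(pe, pool)
  expect_equal(unname(ge$rpm["gA", "s1"]), unname(pe$rpm["gA_p2", "s1"]))

  # even primer count: mean of the middle two
  pool2 <- make_test_pool(c(100L, 200L, 300L, 400L))
  pe2 <- primer_expression(
    assign_to_primers(
      toy_alignments(rep(c(100L, 200L, 300L, 400L), times = c(1, 2, 3, 10)),
                     "+"), pool2),
    pool2)
  ge2 <- gene_expression_from_primers(pe2, pool2)
  expect_equal(unname(ge2$rpm["gA", "s1"]),
               mean(pe2$rpm[c("gA_p2", "gA_p3"), "s1"]))
})

test_that("the median damps a planted 10x outlier across 12 primers", {
  coords <- seq(100L, by = 50L, length.out = 12L)
  pool <- make_test_pool(coords)
  per_primer <- rep(50L, 12)
  per_primer[7] <- 500L  # one over-efficient primer
  aln <- toy_alignments(rep(coords, times = per_primer), "+")
  ge <- gene_expression_from_primers(
    primer_expression(assign_to_primers(aln, pool), pool), pool)
  cluster_rpm <- 50 / sum(per_primer) * 1e6
  expect_equal(unname(ge$rpm["gA", "s1"]), cluster_rpm, tolerance = 1e-9)
})

test_that("split-read classification resolves constructed chimeras", {
  set.seed(42)
  genome <- c(chr1 = random_dna(3000))
  primer_seq <- substr(genome[["chr1"]], 501, 520)
  pool <- make_test_pool(500L)
  pool$primers$sequence <- primer_seq

  off_target <- substr(genome[["chr1"]], 2001, 2030)
  chimera <- toy_reads(paste0(primer_seq, off_target))
  ev <- classify_misprimes(chimera, genome, pool)
  expect_identical(nrow(ev), 1L)
  expect_true(ev$resolved)
  expect_identical(ev$primer_id, "gA_p1")
  expect_identical(ev$misprime_contig, "chr1")
  expect_identical(ev$misprime_pos, 2000L)

  # a 10-nt tail is below min_tail: event emitted but unresolved
  short_tail <- toy_reads(paste0(primer_seq, substr(off_target, 1, 10)))
  ev2 <- classify_misprimes(short_tail, genome, pool)
  expect_identical(nrow(ev2), 1L)
  expect_false(ev2$resolved)

  # head mapping nowhere emits nothing
  alien <- toy_reads(paste0(strrep("ACN", 7), substr(off_target, 1, 29)))
  expect_identical(nrow(classify_misprimes(alien, genome, pool)), 0L)

  # reads shorter than the head are skipped with a warning
  expect_warning(out <- classify_misprimes(toy_reads("ACGTACGT"), genome, pool),
                 "shorter than head_len")
  expect_identical(nrow(out), 0L)
})

test_that("specific reads with untrimmable poly(A) stubs never resolve as chimeras", {
  set.seed(43)
  genome <- c(chr1 = paste0(random_dna(545), "CCGGC", random_dna(2450)))
  primer_seq <- substr(genome[["chr1"]], 501, 520)
  pool <- make_test_pool(500L)
  pool$primers$sequence <- primer_seq

  # a 5-A stub is too short to trim but blocks end-to-end mapping; the
  # tail inherits the same stub, so the event stays unresolved
  specific <- toy_reads(paste0(substr(genome[["chr1"]], 501, 545),
                               strrep("A", 5)))
  expect_identical(trim_polya(specific)$sequence, specific$sequence)
  expect_identical(nrow(map_reads(specific, genome)$alignments), 0L)
  ev <- classify_misprimes(specific, genome, pool)
  expect_identical(nrow(ev), 1L)
  expect_false(ev$resolved)

  # a head with two errors plus a one-error contiguous tail is unmapped
  # end-to-end (3 mismatches) yet clearly specific: the tail maps right
  # where extension of the head would sit, so no event is emitted
  head <- primer_seq
  substr(head, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(head, 3, 3))[1]
  substr(head, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(head, 11, 11))[1]
  tail <- substr(genome[["chr1"]], 521, 550)
  substr(tail, 15, 15) <- setdiff(c("A", "C", "G", "T"), substr(tail, 15, 15))[1]
  noisy_specific <- toy_reads(paste0(head, tail))
  expect_identical(nrow(map_reads(noisy_specific, genome)$alignments), 0L)
  expect_identical(nrow(classify_misprimes(noisy_specific, genome, pool)), 0L)
})

test_that("agreement statistics behave under self-pairing and scaling", {
  set.seed(44)
  base <- rpois(40, 2000) + 200L
  counts <- cbind(s1 = base, s2 = base * 3L)
  rownames(counts) <- sprintf("g%02d", 1:40)
  tab <- table_from_counts(counts)
  st <- agreement_stats(tab)
  # scaled counts differ only by a log shift: r is exactly 1
  expect_equal(unname(st$pairwise_r["s1", "s2"]), 1, tolerance = 1e-12)
  expect_equal(unname(diag(st$pairwise_r)), c(1, 1))
})

test_that("median SD of log2 expression recovers injected multiplicative noise", {
  set.seed(45)
  n_genes <- 60; n_samples <- 8
  sd_log2 <- 0.25
  mu <- runif(n_genes, 3.2, 5)  # log10 mean expression, all above threshold
  expr <- matrix(10^mu, n_genes, n_samples) *
    2^matrix(rnorm(n_genes * n_samples, 0, sd_log2), n_genes, n_samples)
  counts <- round(expr)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sprintf("g%02d", 1:n_genes),
                           sprintf("s%d", 1:n_samples))
  tab <- table_from_counts(counts)
  st <- agreement_stats(tab)
  # direct oracle: same summary computed straight from the count matrix
  rpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  direct <- median(apply(log2(rpm), 1, sd))
  expect_equal(st$median_sd_log2fc, direct, tolerance = 1e-12)
  # and the injected noise scale is recovered within Monte-Carlo error
  expect_lt(abs(st$median_sd_log2fc - sd_log2), 0.05)
})

test_that("pairs sharing too few features are flagged", {
  counts <- matrix(c(500L, 50L, 50L, 500L), ncol = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  tab <- table_from_counts(counts)
  st <- agreement_stats(tab)
  expect_true(is.na(st$pairwise_r["s1", "s2"]))
  expect_identical(st$flagged_pairs, "s1:s2")
})
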