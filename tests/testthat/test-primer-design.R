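# Primer pool design: candidate enumeration, rRNA word filtering, spaced
# selection, adapter appending, and the independent pool validator.

test_that("design defaults carry the published constraint set", {
  p <- design_params()
  expect_identical(c(p$min_len, p$opt_len, p$max_len), c(18L, 20L, 22L))
  expect_identical(c(p$tm_min, p$tm_opt, p$tm_max), c(53, 55, 56))
  expect_identical(p$rrna_word, 8L)
  expect_identical(p$min_spacing, 20L)
  expect_identical(p$adapter, "CTTTCCCTACACGACGCTCTTCCGATCT")
})

test_that("candidate enumeration equals the exhaustive window oracle", {
  set.seed(21)
  genome <- c(chr1 = random_dna(400))
  params <- design_params()
  for (strand in c("+", "-")) {
    gene <- list(gene_id = "gX", contig = "chr1", strand = strand,
                 start = 50L, end = 350L)
    got <- generate_candidates(
      toy_genes(list("gX", "chr1", strand, 50, 350, "CDS"))[1, ],
      genome, params)
    exp <- oracle_candidate_windows(gene, genome, params)
    expect_gt(nrow(got), 0)
    expect_equal(got[c("tx_start", "length", "sequence")],
                 exp[c("tx_start", "length", "sequence")],
                 ignore_attr = TRUE)
    expect_equal(got$tm, exp$tm, tolerance = 1e-9)
    expect_equal(got$penalty, exp$penalty, tolerance = 1e-9)
    # genomic coordinates recover the coding-strand sequence
    for (i in sample(nrow(got), 5)) {
      s <- substr(genome[["chr1"]], got$anneal_start[i] + 1L, got$anneal_end[i])
      if (strand == "-") s <- rc_chr(s)
      expect_identical(s, got$sequence[i])
    }
  }
})

test_that("genes shorter than min_len yield an empty candidate list", {
  genome <- c(chr1 = random_dna(100))
  g <- toy_genes(list("tiny", "chr1", "+", 10, 20, "CDS"))
  expect_identical(nrow(generate_candidates(g[1, ], genome)), 0L)
})

test_that("rRNA word filtering matches a brute-force scan and is idempotent", {
  set.seed(22)
  genome <- c(chr1 = paste0(random_dna(300), random_dna(200)))
  genes <- toy_genes(list("gX", "chr1", "+", 0, 300, "CDS"),
                     list("rrn1", "chr1", "+", 300, 500, "rRNA"))
  params <- design_params()
  cand <- generate_candidates(genes[1, ], genome, params)
  rrna <- genes[2, , drop = FALSE]
  rrna_seq <- substr(genome[["chr1"]], 301, 500)

  # empty region list: vacuous filter
  expect_identical(filter_rrna_words(cand, rrna[0, ], genome, params), cand)

  kept <- filter_rrna_words(cand, rrna, genome, params)
  oracle_hit <- vapply(cand$sequence, oracle_shares_rrna_word,
                       logical(1), rrna_seqs = rrna_seq, k = params$rrna_word,
                       USE.NAMES = FALSE)
  expect_identical(kept$sequence, cand$sequence[!oracle_hit])
  expect_identical(filter_rrna_words(kept, rrna, genome, params), kept)
})

test_that("a candidate containing the reverse complement of an rRNA 8-mer is removed", {
  set.seed(23)
  word <- "ACGGTTCA"
  genome <- c(chr1 = paste0(random_dna(100), word, random_dna(92)))
  rrna <- toy_genes(list("rrn1", "chr1", "+", 100, 108, "rRNA"))
  clean <- "CTCTCTCTGAGAGAGACTCT"  # shares no 8-mer with the word
  cand <- data.frame(
    gene_id = "g1", contig = "chr1", target_strand = "+",
    anneal_start = c(0L, 30L), anneal_end = c(20L, 50L),
    tx_start = c(0L, 30L), length = 20L,
    sequence = c(paste0(random_dna(6), rc_chr(word), random_dna(6)), clean),
    tm = 55, penalty = 0, stringsAsFactors = FALSE)
  kept <- filter_rrna_words(cand, rrna, genome)
  expect_identical(kept$sequence, clean)
  # agreement with the brute-force both-strand scan
  expect_identical(
    vapply(cand$sequence, oracle_shares_rrna_word, logical(1),
           rrna_seqs = word, k = 8L, USE.NAMES = FALSE),
    c(TRUE, FALSE))
})

test_that("spaced selection admits one primer when the spacing rule blocks the second", {
  cand <- data.frame(
    gene_id = "g1", contig = "c", target_strand = "+",
    anneal_start = c(100L, 110L), anneal_end = c(120L, 130L),
    tx_start = c(0L, 10L), length = c(20L, 20L),
    sequence = c(strrep("AC", 10), strrep("GT", 10)),
    tm = c(55, 55), penalty = c(0, 0), stringsAsFactors = FALSE)
  pool <- select_spaced(cand)
  expect_identical(nrow(pool$primers), 1L)
  expect_identical(pool$primers$tx_start, 0L)  # the most upstream one

  # a single candidate faces no constraint
  expect_identical(nrow(select_spaced(cand[1, ])$primers), 1L)
})

test_that("greedy selection yields a valid maximal chain", {
  set.seed(24)
  params <- design_params()
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    cand <- data.frame(
      gene_id = "g1", contig = "c", target_strand = "+",
      tx_start = sort(sample(0:300, n, replace = TRUE)),
      length = sample(18:22, n, replace = TRUE),
      tm = runif(n, 53, 56), penalty = runif(n, 0, 3),
      stringsAsFactors = FALSE)
    cand$anneal_start <- 1000L + cand$tx_start
    cand$anneal_end <- cand$anneal_start + cand$length
    cand$sequence <- vapply(cand$length, random_dna, character(1))
    sel <- select_spaced(cand, params)$primers
    sel <- sel[order(sel$tx_start), , drop = FALSE]
    tx3 <- sel$tx_start + sel$length - 1L
    # validity: every consecutive pair respects the spacing rule
    if (nrow(sel) > 1L)
      expect_true(all(sel$tx_start[-1L] - tx3[-nrow(sel)] >= params$min_spacing))
    # maximality: no rejected candidate fits anywhere in the chain
    rejected <- cand[!paste(cand$tx_start, cand$sequence) %in%
                       paste(sel$tx_start, sel$sequence), , drop = FALSE]
    for (i in seq_len(nrow(rejected))) {
      r5 <- rejected$tx_start[i]
      r3 <- r5 + rejected$length[i] - 1L
      up <- tx3[sel$tx_start < r5]
      down <- sel$tx_start[sel$tx_start >= r5]
      ok_up <- length(up) == 0L || r5 - max(up) >= params$min_spacing
      ok_down <- length(down) == 0L || min(down) - r3 >= params$min_spacing
      expect_false(ok_up && ok_down)
    }
  }
})

test_that("adapter appending builds oligos without touching primer fields", {
  cand <- data.frame(
    gene_id = "g1", contig = "c", target_strand = "+",
    anneal_start = 0L, anneal_end = 20L, tx_start = 0L, length = 20L,
    sequence = "ACGTACGTACGTACGTACGT", tm = 55, penalty = 0,
    stringsAsFactors = FALSE)
  pool <- append_adapter(select_spaced(cand))
  expect_identical(pool$primers$oligo,
                   "CTTTCCCTACACGACGCTCTTCCGATCTACGTACGTACGTACGTACGT")
  expect_identical(nchar(pool$primers$oligo), 28L + nchar(pool$primers$sequence))
  expect_identical(substr(pool$primers$oligo,
                          nchar(pool$primers$oligo) - nchar(pool$primers$sequence) + 1L,
                          nchar(pool$primers$oligo)),
                   pool$primers$sequence)
})

test_that("designed pools pass the independent validator; corrupted pools fail", {
  cfg <- sim_config(seed = 25, n_genes = 6, gene_length_range = c(300L, 500L),
                    rrna_length = 600L)
  ref <- make_reference(cfg)
  pool <- design_primer_pool(ref$genome, ref$genes)
  expect_gt(nrow(pool$primers), 0)
  expect_true(validate_primer_pool(pool, ref$genome, ref$genes))

  bad <- pool
  bad$primers$oligo[1] <- paste0("T", substr(bad$primers$oligo[1], 2,
                                             nchar(bad$primers$oligo[1])))
  expect_error(validate_primer_pool(bad, ref$genome, ref$genes),
               "adapter")
  bad2 <- pool
  bad2$primers$sequence[1] <- rc_chr(bad2$primers$sequence[1])
  bad2$primers$oligo[1] <- paste0(pool$adapter, bad2$primers$sequence[1])
  expect_error(validate_primer_pool(bad2, ref$genome, ref$genes))
})

test_that("identical inputs give byte-identical primer manifests", {
  cfg <- sim_config(seed = 26, n_genes = 4, gene_length_range = c(300L, 400L))
  ref <- make_reference(cfg)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_primer_manifest(design_primer_pool(ref$genome, ref$genes), f1)
  write_primer_manifest(design_primer_pool(ref$genome, ref$genes), f2)
  expect_identical(readLines(f1), readLines(f2))
})
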