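# Truth-tracked read simulator emulating the multiplexed (poly(A)-tailed,
# barcoded) and targeted (second-strand primed) data-generating processes,
# so every pipeline stage can be tested against known ground truth.

.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults describe a small but realistic bacterial benchmark: a
#' log-normal transcriptome skewed so the top 1% of genes carry about 30%
#' of reads (`abundance_sigma = 1.802`, the analytic value for that
#' share), CDS-sized genes, gel-selected fragment lengths larger than the
#' read length, enzymatic poly(A) tails of 8--25 nt, and per-pair barcode
#' switching of 1%. `switch_rate` is the probability that a read is
#' emitted under one specific other sample's barcode — the quantity the
#' knockout estimator reports — so the total probability of switching
#' anywhere is `switch_rate * (n_samples - 1)`.
#'
#' @param seed integer seed; together with the config it fully determines
#'   all output. Per-stage substreams are derived from it, so adding
#'   stages never perturbs earlier draws.
#' @param n_genes number of protein-coding genes.
#' @param gene_length_range min/max gene length (nt).
#' @param abundance_sigma log-normal sigma of transcript abundances.
#' @param rrna_fraction fraction of reads drawn from rRNA (0 =
#'   pre-depleted input; ~0.9 emulates total RNA).
#' @param n_rrna,rrna_length number and length of rRNA regions.
#' @param intergenic_range min/max intergenic gap (nt).
#' @param genome_length optional fixed genome length; features must fit.
#' @param n_samples number of barcoded samples.
#' @param reads_per_sample reads emitted per sample.
#' @param fragment_length_range min/max RNA fragment length (nt).
#' @param polya_tail_range min/max poly(A) tail length (nt).
#' @param read_length sequencing read length (nt).
#' @param misprime_rate probability a targeted read is a primer-initiated
#'   chimera (off-target body).
#' @param switch_rate per-pair barcode-switching probability.
#' @param tail_error_rate per-base error rate inside simulated poly(A)
#'   tails (stress knob for the trimmer; default 0 = pure A).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 100L,
                       gene_length_range = c(400L, 1200L),
                       abundance_sigma = 1.802, rrna_fraction = 0,
                       n_rrna = 2L, rrna_length = 1200L,
                       intergenic_range = c(40L, 120L),
                       genome_length = NULL,
                       n_samples = 6L, reads_per_sample = 1e5,
                       fragment_length_range = c(70L, 120L),
                       polya_tail_range = c(8L, 25L), read_length = 50L,
                       misprime_rate = 0.1, switch_rate = 0.01,
                       tail_error_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              abundance_sigma = abundance_sigma,
              rrna_fraction = rrna_fraction, n_rrna = as.integer(n_rrna),
              rrna_length = as.integer(rrna_length),
              intergenic_range = as.integer(intergenic_range),
              genome_length = genome_length,
              n_samples = as.integer(n_samples),
              reads_per_sample = as.integer(reads_per_sample),
              fragment_length_range = as.integer(fragment_length_range),
              polya_tail_range = as.integer(polya_tail_range),
              read_length = as.integer(read_length),
              misprime_rate = misprime_rate, switch_rate = switch_rate,
              tail_error_rate = tail_error_rate)
  for (f in c("rrna_fraction", "misprime_rate", "switch_rate", "tail_error_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) .stopf("sim_config: %s must be in [0,1]", f)
  }
  if (cfg$switch_rate * (cfg$n_samples - 1L) > 1)
    .stopf("sim_config: switch_rate * (n_samples - 1) must be <= 1")
  for (f in c("gene_length_range", "intergenic_range",
              "fragment_length_range", "polya_tail_range")) {
    if (length(cfg[[f]]) != 2L || cfg[[f]][1L] > cfg[[f]][2L] || cfg[[f]][1L] < 0L)
      .stopf("sim_config: %s must be a non-empty range", f)
  }
  if (cfg$abundance_sigma < 0) .stopf("sim_config: abundance_sigma must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

.runif_int <- function(n, lo, hi) {
  if (lo == hi) rep.int(as.integer(lo), n)
  else as.integer(lo + floor(runif(n) * (hi - lo + 1)))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random reference genome and annotation
#'
#' One contig holding `n_genes` non-overlapping CDS genes on random
#' strands plus `n_rrna` rRNA regions, separated by random intergenic
#' gaps; the sequence is uniform random DNA. Deterministic per seed; the
#' output passes the package's genome and gene-model validators.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character) and `genes` (gene model
#'   data.frame).
#' @export
make_reference <- function(config) {
  set.seed(.stage_seed(config$seed, 1L))
  n_feat <- config$n_genes + config$n_rrna
  kinds <- rep("CDS", n_feat)
  if (config$n_rrna > 0L && n_feat > 0L) {
    # spread rRNA regions evenly among the features
    at <- as.integer(round(seq(1L, n_feat,
                               length.out = config$n_rrna + 2L)))[seq_len(config$n_rrna) + 1L]
    at <- unique(pmin(pmax(at, 1L), n_feat))
    if (length(at) < config$n_rrna) {
      free <- setdiff(seq_len(n_feat), at)
      at <- c(at, free[seq_len(config$n_rrna - length(at))])
    }
    kinds[at] <- "rRNA"
  }
  lens <- integer(n_feat)
  lens[kinds == "CDS"] <- .runif_int(config$n_genes,
                                     config$gene_length_range[1L],
                                     config$gene_length_range[2L])
  lens[kinds == "rRNA"] <- config$rrna_length
  gaps <- .runif_int(n_feat + 1L, config$intergenic_range[1L],
                     config$intergenic_range[2L])
  starts <- integer(n_feat)
  cur <- gaps[1L]
  for (i in seq_len(n_feat)) {
    starts[i] <- cur
    cur <- cur + lens[i] + gaps[i + 1L]
  }
  glen <- if (is.null(config$genome_length)) max(cur, 200L)
          else as.integer(config$genome_length)
  if (cur > glen)
    .stopf("make_reference: %d features need %d nt but genome_length is %d",
           n_feat, cur, glen)
  genome <- setNames(.random_dna(glen), "sim1")
  strand <- character(n_feat)
  gi <- kinds == "CDS"
  strand[gi] <- sample(c("+", "-"), sum(gi), replace = TRUE)
  strand[!gi] <- "+"
  ids <- character(n_feat)
  ids[gi] <- sprintf("g%03d", seq_len(sum(gi)))
  ids[!gi] <- sprintf("rrn%d", seq_len(sum(!gi)))
  genes <- data.frame(gene_id = ids, contig = rep("sim1", n_feat),
                      strand = strand, start = starts, end = starts + lens,
                      feature_class = kinds, stringsAsFactors = FALSE)
  if (n_feat > 0L) validate_gene_models(genes, genome)
  list(genome = genome, genes = genes)
}

#' Sample a skewed transcript abundance vector
#'
#' Log-normal relative abundances normalised to sum to 1. The default
#' sigma of 1.802 solves `pnorm(sigma - qnorm(0.99)) = 0.30`, i.e. the top
#' 1% of genes carry 30% of transcripts in expectation; `sigma = 0` gives
#' uniform abundances.
#'
#' @param config a [sim_config()].
#' @return numeric vector of length `n_genes` summing to 1.
#' @export
sample_abundances <- function(config) {
  set.seed(.stage_seed(config$seed, 2L))
  if (config$n_genes == 0L) return(numeric(0))
  w <- rlnorm(config$n_genes, meanlog = 0, sdlog = config$abundance_sigma)
  w / sum(w)
}

.coding_sequences <- function(genes, genome) {
  vapply(seq_len(nrow(genes)), function(i) {
    .gene_coding_sequence(genes[i, ], genome)
  }, character(1))
}

.apply_switching <- function(true_sample, config) {
  n <- length(true_sample)
  ns <- config$n_samples
  emitted <- true_sample
  if (ns > 1L && config$switch_rate > 0) {
    sw <- runif(n) < config$switch_rate * (ns - 1L)
    off <- .runif_int(n, 1L, ns - 1L)
    emitted[sw] <- ((true_sample[sw] - 1L + off[sw]) %% ns) + 1L
  }
  emitted
}

.make_tails <- function(n, config) {
  tail_len <- .runif_int(n, config$polya_tail_range[1L],
                         config$polya_tail_range[2L])
  tails <- strrep("A", tail_len)
  if (config$tail_error_rate > 0 && n > 0L) {
    tails <- vapply(tails, function(t) {
      b <- strsplit(t, "", fixed = TRUE)[[1L]]
      err <- runif(length(b)) < config$tail_error_rate
      b[err] <- sample(c("C", "G", "T"), sum(err), replace = TRUE)
      paste(b, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  tails
}

.sim_read_frame <- function(ids, emitted, seqs) {
  data.frame(read_id = ids, sample_id = sprintf("sample%02d", emitted),
             sequence = seqs, quality = strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}

# Abundances may be a single vector (all samples alike) or a matrix with
# one column per sample (e.g. a knockout sample with one gene zeroed).
.abundance_matrix <- function(abundances, n_genes, n_samples, what) {
  if (is.matrix(abundances)) {
    if (nrow(abundances) != n_genes || ncol(abundances) != n_samples)
      .stopf("%s: abundance matrix must be n_genes x n_samples", what)
    abundances
  } else {
    if (length(abundances) != n_genes)
      .stopf("%s: abundances must match the CDS genes", what)
    matrix(rep(abundances, n_samples), ncol = n_samples)
  }
}

# draw one source index per selected read, with its true sample's weights
.sample_sources <- function(slots, true_sample, W) {
  out <- integer(length(slots))
  ts <- true_sample[slots]
  for (s in unique(ts)) {
    sel <- ts == s
    out[sel] <- sample.int(nrow(W), sum(sel), replace = TRUE, prob = W[, s])
  }
  out
}

#' Simulate multiplexed (non-targeted) reads
#'
#' Emulates the multiplexed workflow: each read picks a gene proportional
#' to abundance (or an rRNA region with probability `rrna_fraction`,
#' proportional to region length), a fragment uniformly within it, gains a
#' poly(A) tail, is truncated to the read length, and is emitted under its
#' sample's barcode except for barcode-switching events, which are emitted
#' under a uniformly chosen other sample. Every read's provenance is
#' recorded in the truth table.
#'
#' @param reference output of [make_reference()].
#' @param abundances abundance vector over the CDS genes (see
#'   [sample_abundances()]), or a matrix with one column per sample
#'   (e.g. a knockout sample with one gene zeroed).
#' @param config a [sim_config()].
#' @return list with `reads` (read data.frame across all samples) and
#'   `truth` (per-read provenance: true/emitted sample, source feature,
#'   fragment coordinates, tail length).
#' @export
simulate_bam_reads <- function(reference, abundances, config) {
  force(reference); force(abundances)  # before seeding: args may draw RNG
  set.seed(.stage_seed(config$seed, 3L))
  genes <- reference$genes[reference$genes$feature_class == "CDS", , drop = FALSE]
  rrna <- reference$genes[reference$genes$feature_class == "rRNA", , drop = FALSE]
  A <- .abundance_matrix(abundances, nrow(genes), config$n_samples,
                         "simulate_bam_reads")
  N <- config$n_samples * config$reads_per_sample
  if (N == 0L || (nrow(genes) == 0L && config$rrna_fraction == 0))
    .stopf("simulate_bam_reads: nothing to simulate")
  true_sample <- rep(seq_len(config$n_samples), each = config$reads_per_sample)

  from_rrna <- runif(N) < config$rrna_fraction & nrow(rrna) > 0L
  if (nrow(genes) == 0L) from_rrna[] <- TRUE  # no CDS: all reads are rRNA
  src <- integer(N)
  if (any(!from_rrna))
    src[!from_rrna] <- .sample_sources(which(!from_rrna), true_sample, A)
  if (any(from_rrna))
    src[from_rrna] <- sample.int(nrow(rrna), sum(from_rrna), replace = TRUE,
                                 prob = rrna$end - rrna$start)
  feat <- rbind(genes, rrna)
  fidx <- ifelse(from_rrna, nrow(genes) + src, src)
  flen_feat <- feat$end[fidx] - feat$start[fidx]
  flen <- pmin(.runif_int(N, config$fragment_length_range[1L],
                          config$fragment_length_range[2L]), flen_feat)
  u <- as.integer(floor(runif(N) * (flen_feat - flen + 1L)))
  coding <- .coding_sequences(feat, reference$genome)
  frag <- substring(coding[fidx], u + 1L, u + flen)
  tails <- .make_tails(N, config)
  seqs <- substr(paste0(frag, tails), 1L, config$read_length)
  emitted <- .apply_switching(true_sample, config)
  ids <- sprintf("bam_s%02d_r%07d", true_sample,
                 sequence(rep(config$reads_per_sample, config$n_samples)))
  truth <- data.frame(
    read_id = ids,
    true_sample_id = sprintf("sample%02d", true_sample),
    emitted_sample_id = sprintf("sample%02d", emitted),
    source_id = feat$gene_id[fidx],
    source_class = feat$feature_class[fidx],
    contig = feat$contig[fidx],
    strand = feat$strand[fidx],
    frag_tx_start = u,
    frag_tx_end = u + flen,
    tail_length = nchar(tails),
    primer_id = NA_character_,
    is_misprime = FALSE,
    misprime_contig = NA_character_,
    misprime_strand = NA_character_,
    misprime_pos = NA_integer_,
    stringsAsFactors = FALSE
  )
  list(reads = .sim_read_frame(ids, emitted, seqs), truth = truth,
       config = config)
}

#' Simulate targeted (second-strand primed) reads
#'
#' Emulates target enrichment: each read chooses a pool primer with
#' probability proportional to its gene's abundance times a per-primer
#' efficiency (equal by default), then reads the transcript from the
#' primer's 5' end through the 3' end of a fragment containing the priming
#' site, runs into the poly(A) tail, and is truncated to the read length.
#' With probability `misprime_rate` the read is instead a primer-initiated
#' chimera: the primer sequence followed by a body drawn from a uniformly
#' random off-target genomic locus (recorded in the truth table). Barcode
#' switching is applied as in [simulate_bam_reads()].
#'
#' @param reference output of [make_reference()].
#' @param abundances abundance vector over the CDS genes, or a matrix with
#'   one column per sample.
#' @param pool a `primer_pool` designed on the same reference.
#' @param config a [sim_config()].
#' @param primer_efficiency optional positive per-primer efficiency vector
#'   (default: equal).
#' @return list with `reads` and `truth` as in [simulate_bam_reads()],
#'   with `primer_id`, `is_misprime` and misprime location filled in.
#' @export
simulate_tbam_reads <- function(reference, abundances, pool, config,
                                primer_efficiency = NULL) {
  force(reference); force(abundances); force(pool); force(primer_efficiency)
  set.seed(.stage_seed(config$seed, 4L))
  p <- pool$primers
  if (nrow(p) == 0L) .stopf("simulate_tbam_reads: primer pool is empty")
  genes <- reference$genes[reference$genes$feature_class == "CDS", , drop = FALSE]
  A <- .abundance_matrix(abundances, nrow(genes), config$n_samples,
                         "simulate_tbam_reads")
  gidx <- match(p$gene_id, genes$gene_id)
  if (any(is.na(gidx)))
    .stopf("simulate_tbam_reads: pool targets a gene absent from the reference")
  eff <- primer_efficiency %||% rep(1, nrow(p))
  if (length(eff) != nrow(p) || any(eff <= 0))
    .stopf("simulate_tbam_reads: primer_efficiency must be positive, one per primer")
  W <- A[gidx, , drop = FALSE] * eff  # per-primer weights, one column/sample
  N <- config$n_samples * config$reads_per_sample
  true_sample <- rep(seq_len(config$n_samples), each = config$reads_per_sample)

  pr <- .sample_sources(seq_len(N), true_sample, W)
  g <- gidx[pr]
  glen <- genes$end[g] - genes$start[g]
  plen <- nchar(p$sequence)[pr]
  tx5 <- ifelse(genes$strand[g] == "+", p$anneal_start[pr] - genes$start[g],
                genes$end[g] - p$anneal_end[pr])
  flen <- pmax(pmin(.runif_int(N, config$fragment_length_range[1L],
                               config$fragment_length_range[2L]), glen), plen)
  # fragment [u, u+flen) must contain the priming site [tx5, tx5+plen)
  u_min <- pmax(0L, tx5 + plen - flen)
  u_max <- pmin(tx5, glen - flen)
  u <- u_min + as.integer(floor(runif(N) * (u_max - u_min + 1L)))
  coding <- .coding_sequences(genes, reference$genome)
  span <- substring(coding[g], tx5 + 1L, u + flen)  # primer 5' -> fragment 3'
  tails <- .make_tails(N, config)
  seqs <- substr(paste0(span, tails), 1L, config$read_length)

  # primer-initiated chimeras: primer head + off-target body
  mis <- runif(N) < config$misprime_rate
  mis_contig <- rep(NA_character_, N)
  mis_strand <- rep(NA_character_, N)
  mis_pos <- rep(NA_integer_, N)
  if (any(mis)) {
    nm <- sum(mis)
    body_len <- pmax(config$read_length - plen[mis], 0L)
    contig_ids <- names(reference$genome)
    ci <- sample.int(length(contig_ids), nm, replace = TRUE,
                     prob = nchar(reference$genome))
    cl <- nchar(reference$genome)[ci]
    bstart <- as.integer(floor(runif(nm) * (cl - body_len + 1L)))
    bstrand <- sample(c("+", "-"), nm, replace = TRUE)
    body <- substring(reference$genome[ci], bstart + 1L, bstart + body_len)
    body[bstrand == "-"] <- revcomp(body[bstrand == "-"])
    seqs[mis] <- substr(paste0(p$sequence[pr[mis]], body), 1L,
                        config$read_length)
    mis_contig[mis] <- contig_ids[ci]
    mis_strand[mis] <- bstrand
    # 5' coordinate of the body in the adjusted-position convention
    mis_pos[mis] <- ifelse(bstrand == "+", bstart, bstart + body_len)
  }
  emitted <- .apply_switching(true_sample, config)
  ids <- sprintf("tbam_s%02d_r%07d", true_sample,
                 sequence(rep(config$reads_per_sample, config$n_samples)))
  truth <- data.frame(
    read_id = ids,
    true_sample_id = sprintf("sample%02d", true_sample),
    emitted_sample_id = sprintf("sample%02d", emitted),
    source_id = genes$gene_id[g],
    source_class = "CDS",
    contig = genes$contig[g],
    strand = genes$strand[g],
    frag_tx_start = u,
    frag_tx_end = u + flen,
    tail_length = nchar(tails),
    primer_id = p$primer_id[pr],
    is_misprime = mis,
    misprime_contig = mis_contig,
    misprime_strand = mis_strand,
    misprime_pos = mis_pos,
    stringsAsFactors = FALSE
  )
  list(reads = .sim_read_frame(ids, emitted, seqs), truth = truth,
       config = config)
}
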