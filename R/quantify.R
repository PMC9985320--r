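# Gene- and primer-level quantification, mispriming classification, and
# replicate-agreement statistics.

.new_expression_table <- function(counts, feature_kind, min_reads_report,
                                  denominator_policy) {
  structure(list(counts = counts, rpm = NULL,
                 denominators = rep(NA_real_, ncol(counts)),
                 feature_kind = feature_kind,
                 min_reads_report = as.integer(min_reads_report),
                 denominator_policy = denominator_policy,
                 flagged_samples = character(0)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("Expression table (%s-level): %d features x %d samples\n",
              x$feature_kind, nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total counts per sample: %s\n",
              paste(colSums(x$counts), collapse = ", ")))
  if (!is.null(x$rpm))
    cat(sprintf("  rpm computed (%s; reported where counts > %d in gene mode)\n",
                x$denominator_policy, x$min_reads_report))
  if (length(x$flagged_samples))
    cat(sprintf("  flagged samples (zero denominator): %s\n",
                paste(x$flagged_samples, collapse = ", ")))
  invisible(x)
}

.require_adjusted <- function(alignments) {
  if (is.null(alignments$adj_pos))
    .stopf("alignments must carry adj_pos; run adjust_positions() first")
  alignments
}

#' Count 5'-mapped reads per gene with CDS edge exclusion
#'
#' A read contributes to gene `g` iff its adjusted 5' position falls within
#' the gene body excluding the first and last `edge_exclusion` nt in
#' transcript orientation, and the strands agree. Each read counts at most
#' once; reads whose 5' position lies in the countable window of more than
#' one gene are dropped (deterministic, conservative). Genes shorter than
#' `2 * edge_exclusion` are reported with a zero countable region (warning,
#' not error).
#'
#' @param alignments adjusted alignments (see [adjust_positions()]).
#' @param genes gene model data.frame.
#' @param edge_exclusion nt excluded at each CDS end (default 30).
#' @param samples optional character vector fixing the sample set and
#'   order (default: the samples present in `alignments`).
#' @return an `expression_table` with `feature_kind = "gene"` (counts only;
#'   see [compute_rpm()]).
#' @export
count_gene_reads <- function(alignments, genes, edge_exclusion = 30L,
                             samples = NULL) {
  .require_adjusted(alignments)
  validate_gene_models(genes)
  e <- as.integer(edge_exclusion)
  short <- (genes$end - genes$start) < 2L * e + 1L
  if (any(short))
    .warnf("%d gene(s) shorter than 2*edge_exclusion have zero countable region (first: %s)",
           sum(short), genes$gene_id[short][1L])
  samples <- samples %||% sort(unique(alignments$sample_id))
  counts <- matrix(0L, nrow = nrow(genes), ncol = length(samples),
                   dimnames = list(genes$gene_id, samples))
  usable <- genes[!short, , drop = FALSE]
  al <- alignments[alignments$contig %in% unique(usable$contig), , drop = FALSE]
  if (nrow(al) > 0L && nrow(usable) > 0L) {
    # 5' base: adj_pos for forward reads, adj_pos - 1 for reverse reads
    # (reverse adj_pos is one past the 5' base, by the adjustment rule).
    point <- ifelse(al$strand == "-", al$adj_pos - 1L, al$adj_pos)
    win <- GenomicRanges::GRanges(
      seqnames = usable$contig,
      ranges = IRanges::IRanges(start = usable$start + e + 1L,
                                end = usable$end - e),
      strand = usable$strand
    )
    pts <- GenomicRanges::GRanges(
      seqnames = factor(al$contig, levels = GenomeInfoDb::seqlevels(win)),
      ranges = IRanges::IRanges(start = point + 1L, width = 1L),
      strand = al$strand
    )
    ov <- GenomicRanges::findOverlaps(pts, win, ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(ov)
    amb <- unique(qh[duplicated(qh)])
    if (length(amb)) {
      message(sprintf("count_gene_reads: dropping %d read(s) in ambiguous countable windows",
                      length(amb)))
      keep <- !(qh %in% amb)
      ov <- ov[keep]
      qh <- qh[keep]
    }
    if (length(ov)) {
      tab <- table(
        factor(usable$gene_id[S4Vectors::subjectHits(ov)], levels = genes$gene_id),
        factor(al$sample_id[qh], levels = samples)
      )
      counts <- counts + as.matrix(unclass(tab))
    }
  }
  storage.mode(counts) <- "integer"
  .new_expression_table(counts, "gene", 100L, "all_feature_reads")
}

#' Compute reads-per-million with reporting threshold
#'
#' The per-sample denominator follows the table's policy (all feature
#' counts in the sample, for both gene and primer tables built by this
#' package). In gene mode, rpm is reported (non-`NA`) only for features
#' with strictly more than `min_reads_report` counts in that sample; all
#' counts are retained regardless. A sample with a zero denominator gets
#' all-`NA` rpm and is flagged, never silently zeroed.
#'
#' @param table an `expression_table`.
#' @param min_reads_report reporting threshold (default: the table's,
#'   normally 100).
#' @return the table with `rpm` and `denominators` filled in.
#' @export
compute_rpm <- function(table, min_reads_report = NULL) {
  if (!inherits(table, "expression_table")) .stopf("not an expression_table")
  if (!is.null(min_reads_report))
    table$min_reads_report <- as.integer(min_reads_report)
  counts <- table$counts
  den <- colSums(counts)
  rpm <- sweep(counts, 2L, den, "/") * 1e6
  zero <- den == 0
  if (any(zero)) {
    rpm[, zero] <- NA_real_
    table$flagged_samples <- union(table$flagged_samples,
                                   colnames(counts)[zero])
    .warnf("sample(s) with zero denominator: %s",
           paste(colnames(counts)[zero], collapse = ", "))
  }
  if (table$feature_kind == "gene") {
    rpm[counts <= table$min_reads_report] <- NA_real_
  }
  table$rpm <- rpm
  table$denominators <- den
  table
}

#' Assign adjusted alignments to pool primers
#'
#' A read is assigned to a primer iff its strand equals the read
#' orientation implied by the primer's target strand and its adjusted 5'
#' position lies within `tolerance` nt of the primer's annealing
#' coordinate. The nearest primer wins; reads equidistant from two primers
#' are left unassigned and flagged.
#'
#' @param alignments adjusted alignments (see [adjust_positions()]).
#' @param pool a `primer_pool`.
#' @param tolerance maximum |offset| in nt (default 0: exact coordinate
#'   match).
#' @return data.frame with one row per alignment: `read_id`, `sample_id`,
#'   `primer_id` (`NA` = unassigned), `match_offset`, `tie`.
#' @export
assign_to_primers <- function(alignments, pool, tolerance = 0L) {
  .require_adjusted(alignments)
  p <- pool$primers
  n <- nrow(alignments)
  out <- data.frame(read_id = alignments$read_id,
                    sample_id = alignments$sample_id,
                    primer_id = rep(NA_character_, n),
                    match_offset = rep(NA_integer_, n),
                    tie = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  if (n == 0L || nrow(p) == 0L) return(out)
  akey <- paste(alignments$contig, alignments$strand)
  for (key in unique(paste(p$contig, p$target_strand))) {
    pi <- which(paste(p$contig, p$target_strand) == key)
    ai <- which(akey == key)
    if (length(ai) == 0L) next
    ord <- order(p$anneal_coord[pi], p$primer_id[pi])
    coords <- p$anneal_coord[pi][ord]
    ids <- p$primer_id[pi][ord]
    x <- alignments$adj_pos[ai]
    j <- findInterval(x, coords)  # coords[j] <= x < coords[j+1]
    lo <- pmax(j, 1L)
    hi <- pmin(j + 1L, length(coords))
    d_lo <- abs(x - coords[lo])
    d_hi <- abs(x - coords[hi])
    nearest <- ifelse(d_lo <= d_hi, lo, hi)
    d_near <- pmin(d_lo, d_hi)
    tie <- d_lo == d_hi & lo != hi & d_lo <= tolerance
    ok <- d_near <= tolerance & !tie
    out$primer_id[ai[ok]] <- ids[nearest[ok]]
    out$match_offset[ai[ok]] <- (x - coords[nearest])[ok]
    out$tie[ai[tie]] <- TRUE
  }
  out
}

#' Primer-level expression
#'
#' Counts assigned reads per primer and sample; rpm uses the total number
#' of primer-assigned reads in the sample as denominator, so per-sample
#' primer rpm sums to 1e6. Samples without any assigned read are flagged.
#'
#' @param assignments output of [assign_to_primers()].
#' @param pool a `primer_pool`.
#' @param samples optional character vector fixing the sample set/order.
#' @return an `expression_table` with `feature_kind = "primer"`, rpm
#'   computed.
#' @export
primer_expression <- function(assignments, pool, samples = NULL) {
  samples <- samples %||% sort(unique(assignments$sample_id))
  assigned <- assignments[!is.na(assignments$primer_id), , drop = FALSE]
  counts <- as.matrix(unclass(table(
    factor(assigned$primer_id, levels = pool$primers$primer_id),
    factor(assigned$sample_id, levels = samples)
  )))
  storage.mode(counts) <- "integer"
  tab <- .new_expression_table(counts, "primer", 100L, "primer_mapped_reads")
  compute_rpm(tab)
}

#' Gene expression as the median of its primers' rpm
#'
#' For a gene captured by several primers, expression is the median of its
#' primers' rpm (even count: mean of the middle two). Genes with no primer
#' in the pool are absent from the output.
#'
#' @param primer_table primer-level `expression_table` (rpm computed).
#' @param pool the `primer_pool` supplying the primer-to-gene mapping.
#' @return an `expression_table` with `feature_kind = "gene"` whose `rpm`
#'   holds the median primer rpm and whose `counts` hold the summed primer
#'   counts per gene.
#' @export
gene_expression_from_primers <- function(primer_table, pool) {
  if (is.null(primer_table$rpm)) .stopf("primer table has no rpm; run compute_rpm()")
  map <- setNames(pool$primers$gene_id, pool$primers$primer_id)
  gene_of <- map[rownames(primer_table$counts)]
  genes <- unique(gene_of[!is.na(gene_of)])
  rpm <- do.call(rbind, lapply(genes, function(g) {
    apply(primer_table$rpm[gene_of == g, , drop = FALSE], 2L, median)
  }))
  counts <- do.call(rbind, lapply(genes, function(g) {
    colSums(primer_table$counts[gene_of == g, , drop = FALSE])
  }))
  dimnames(rpm) <- dimnames(counts) <- list(genes, colnames(primer_table$counts))
  storage.mode(counts) <- "integer"
  tab <- .new_expression_table(counts, "gene", primer_table$min_reads_report,
                               "primer_mapped_reads")
  tab$rpm <- rpm
  tab$denominators <- primer_table$denominators
  tab$flagged_samples <- primer_table$flagged_samples
  tab
}

#' Classify mispriming events by split-read remapping
#'
#' Each read that failed to map end-to-end is split at `head_len`; head and
#' tail are mapped independently ([map_reads()] semantics). If the head
#' maps to a priming site (by [assign_to_primers()] on its adjusted
#' position), the read is a nonspecific (misprimed) second-strand event
#' initiated by that primer; the off-target body location is taken from the
#' tail's mapping, or `UNRESOLVED` when the tail is shorter than `min_tail`
#' or unmappable. Reads whose head maps nowhere, or away from any priming
#' site, emit nothing.
#'
#' A candidate whose tail maps contiguously downstream of its own head
#' (within `contiguous_slack` nt, same contig and strand) is discarded:
#' such a read is an ordinary specific read that merely failed end-to-end
#' mapping (for example through an untrimmable few-base poly(A) stub), not
#' a chimera.
#'
#' @param unmapped read data.frame of reads that failed end-to-end mapping.
#' @param genome reference genome.
#' @param pool a `primer_pool`.
#' @param head_len split point: length (nt) of the primer-derived head.
#' @param min_tail minimum tail length (nt) for location resolution.
#' @param max_mismatches mismatch budget for head/tail remapping.
#' @param tolerance primer-matching tolerance for the head (nt).
#' @param contiguous_slack maximum offset (nt) from the head's downstream
#'   continuation at which a tail mapping still marks the read as specific
#'   rather than chimeric.
#' @return data.frame of events: `read_id`, `sample_id`, `primer_id`,
#'   `misprime_contig`, `misprime_strand`, `misprime_pos`, `resolved`.
#' @export
classify_misprimes <- function(unmapped, genome, pool, head_len = 20L,
                               min_tail = 15L, max_mismatches = 2L,
                               tolerance = 0L, contiguous_slack = 2L) {
  empty <- data.frame(read_id = character(0), sample_id = character(0),
                      primer_id = character(0),
                      misprime_contig = character(0),
                      misprime_strand = character(0),
                      misprime_pos = integer(0), resolved = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(unmapped) == 0L) return(empty)
  short <- nchar(unmapped$sequence) < head_len
  if (any(short))
    .warnf("classify_misprimes: skipping %d read(s) shorter than head_len",
           sum(short))
  reads <- unmapped[!short, , drop = FALSE]
  if (nrow(reads) == 0L) return(empty)
  heads <- reads
  heads$sequence <- substr(reads$sequence, 1L, head_len)
  head_map <- map_reads(heads, genome, max_mismatches)
  if (nrow(head_map$alignments) == 0L) return(empty)
  head_aln <- adjust_positions(head_map$alignments)
  asg <- assign_to_primers(head_aln, pool, tolerance)
  hit <- which(!is.na(asg$primer_id))
  if (length(hit) == 0L) return(empty)
  ev_ids <- head_aln$read_id[hit]
  idx <- match(ev_ids, reads$read_id)
  out <- data.frame(read_id = ev_ids,
                    sample_id = head_aln$sample_id[hit],
                    primer_id = asg$primer_id[hit],
                    misprime_contig = NA_character_,
                    misprime_strand = NA_character_,
                    misprime_pos = NA_integer_,
                    resolved = FALSE,
                    stringsAsFactors = FALSE)
  tails <- reads[idx, , drop = FALSE]
  tails$sequence <- substr(tails$sequence, head_len + 1L,
                           nchar(tails$sequence))
  long_enough <- nchar(tails$sequence) >= min_tail
  if (any(long_enough)) {
    tail_map <- map_reads(tails[long_enough, , drop = FALSE], genome,
                          max_mismatches)
    if (nrow(tail_map$alignments) > 0L) {
      taln <- adjust_positions(tail_map$alignments)
      m <- match(out$read_id, taln$read_id)
      got <- !is.na(m)
      out$misprime_contig[got] <- taln$contig[m[got]]
      out$misprime_strand[got] <- taln$strand[m[got]]
      out$misprime_pos[got] <- taln$adj_pos[m[got]]
      out$resolved[got] <- TRUE
    }
  }
  # tails mapping right where specific extension of the head would sit mark
  # ordinary (non-chimeric) reads that merely failed end-to-end mapping
  head_adj <- head_aln$adj_pos[hit]
  head_strand <- head_aln$strand[hit]
  head_contig <- head_aln$contig[hit]
  expected_tail <- ifelse(head_strand == "+", head_adj + head_len,
                          head_adj - head_len)
  contiguous <- out$resolved &
    out$misprime_contig == head_contig &
    out$misprime_strand == head_strand &
    abs(out$misprime_pos - expected_tail) <= contiguous_slack
  contiguous[is.na(contiguous)] <- FALSE
  out <- out[!contiguous, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate-agreement statistics
#'
#' Pairwise Pearson correlation of log10-transformed rpm between samples,
#' and the median across features of the standard deviation of log2 rpm
#' across samples. For each sample pair, features are restricted to those
#' with strictly more than the reporting threshold of counts in both
#' samples of the pair; the median-SD summary uses features passing the
#' threshold in every sample. Pairs sharing fewer than two usable features
#' get an `NA` correlation and are flagged.
#'
#' @param table an `expression_table` with rpm computed and at least two
#'   samples.
#' @return object of class `agreement_stats`: `pairwise_r` (matrix),
#'   `min_r`, `median_sd_log2fc`, `n_features_global`, `flagged_pairs`.
#' @export
agreement_stats <- function(table) {
  if (is.null(table$rpm)) .stopf("run compute_rpm() first")
  counts <- table$counts
  if (ncol(counts) < 2L) .stopf("agreement_stats needs >= 2 samples")
  den <- table$denominators
  expr <- sweep(counts, 2L, den, "/") * 1e6  # unmasked rpm
  pass <- counts > table$min_reads_report
  ns <- ncol(counts)
  r <- matrix(NA_real_, ns, ns, dimnames = list(colnames(counts), colnames(counts)))
  diag(r) <- 1
  flagged <- character(0)
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      keep <- pass[, i] & pass[, j]
      if (sum(keep) < 2L) {
        flagged <- c(flagged, paste(colnames(counts)[c(i, j)], collapse = ":"))
        next
      }
      r[i, j] <- r[j, i] <- cor(log10(expr[keep, i]), log10(expr[keep, j]))
    }
  }
  keep_all <- rowSums(pass) == ns
  med_sd <- if (any(keep_all)) {
    median(apply(log2(expr[keep_all, , drop = FALSE]), 1L, sd))
  } else NA_real_
  structure(list(pairwise_r = r,
                 min_r = suppressWarnings(min(r[upper.tri(r)], na.rm = TRUE)),
                 median_sd_log2fc = med_sd,
                 n_features_global = sum(keep_all),
                 flagged_pairs = flagged),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Replicate agreement across %d samples\n", nrow(x$pairwise_r)))
  cat(sprintf("  minimum pairwise r (log10 rpm): %.4f\n", x$min_r))
  cat(sprintf("  median SD of log2 expression: %.4f (%d features)\n",
              x$median_sd_log2fc, x$n_features_global))
  if (length(x$flagged_pairs))
    cat(sprintf("  pairs with <2 shared features: %s\n",
                paste(x$flagged_pairs, collapse = ", ")))
  invisible(x)
}
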