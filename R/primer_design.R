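# Second-strand target-enrichment primer pool design.
#
# Candidates are exhaustively enumerated windows on the coding strand of
# each target gene, kept when their nearest-neighbor Tm falls in the design
# window, purged of any k-mer shared with rRNA (either strand), and thinned
# by a deterministic greedy 5'->3' scan enforcing a minimum inter-primer
# spacing. The common adapter is appended last to give synthesis oligos.

#' Primer design parameters
#'
#' Defaults: optimal primer length 20 nt (18--22 allowed), melting
#' temperature window 53--56 degrees C with an optimum of 55, rRNA homology
#' word length 8 nt, minimum inter-primer spacing 20 nt, and the common
#' 28-nt adapter `CTTTCCCTACACGACGCTCTTCCGATCT` appended to the 5' end of
#' every primer.
#'
#' @param opt_len optimal primer length (nt).
#' @param max_len maximum primer length (nt).
#' @param min_len minimum primer length (nt).
#' @param tm_min,tm_opt,tm_max melting temperature window and optimum
#'   (degrees C).
#' @param rrna_word length (nt) of the exact-match words screened against
#'   rRNA regions.
#' @param min_spacing minimum distance (nt) from the 3' end of a selected
#'   primer to the 5' end of the next one along the transcript.
#' @param adapter common adapter sequence prepended to every primer.
#' @return an object of class `design_params`.
#' @export
design_params <- function(opt_len = 20L, max_len = 22L, min_len = 18L,
                          tm_min = 53, tm_opt = 55, tm_max = 56,
                          rrna_word = 8L, min_spacing = 20L,
                          adapter = "CTTTCCCTACACGACGCTCTTCCGATCT") {
  p <- list(opt_len = as.integer(opt_len), max_len = as.integer(max_len),
            min_len = as.integer(min_len), tm_min = tm_min, tm_opt = tm_opt,
            tm_max = tm_max, rrna_word = as.integer(rrna_word),
            min_spacing = as.integer(min_spacing), adapter = toupper(adapter))
  if (!(p$min_len <= p$opt_len && p$opt_len <= p$max_len))
    .stopf("design_params: need min_len <= opt_len <= max_len")
  if (!(p$tm_min <= p$tm_opt && p$tm_opt <= p$tm_max))
    .stopf("design_params: need tm_min <= tm_opt <= tm_max")
  if (p$rrna_word < 1L) .stopf("design_params: rrna_word must be >= 1")
  if (!nzchar(p$adapter)) .stopf("design_params: adapter must be non-empty")
  class(p) <- "design_params"
  p
}

.gene_coding_sequence <- function(gene, genome) {
  s <- substr(genome[[gene$contig]], gene$start + 1L, gene$end)
  if (gene$strand == "-") revcomp(s) else s
}

.empty_candidates <- function() {
  data.frame(gene_id = character(0), contig = character(0),
             target_strand = character(0), anneal_start = integer(0),
             anneal_end = integer(0), tx_start = integer(0),
             length = integer(0), sequence = character(0),
             tm = numeric(0), penalty = numeric(0), stringsAsFactors = FALSE)
}

#' Enumerate primer candidates for one gene
#'
#' Every window of length `min_len`..`max_len` that lies fully inside the
#' gene's coding-strand sequence is evaluated; windows whose
#' nearest-neighbor Tm falls inside `[tm_min, tm_max]` become candidates
#' with penalty `|tm - tm_opt| + 0.5 * |len - opt_len|`. Windows containing
#' `N` are skipped (N never matches anything). Candidates are sorted by
#' transcript coordinate, then penalty, then sequence.
#'
#' @param gene a single gene model (one-row data.frame or list with fields
#'   `gene_id`, `contig`, `strand`, `start`, `end`).
#' @param genome reference genome (named character vector).
#' @param params a [design_params()] object.
#' @return candidate data.frame with columns `gene_id`, `contig`,
#'   `target_strand`, `anneal_start`, `anneal_end`, `tx_start` (0-based 5'
#'   offset along the transcript), `length`, `sequence`, `tm`, `penalty`.
#' @export
generate_candidates <- function(gene, genome, params = design_params()) {
  gene <- as.list(gene[c("gene_id", "contig", "strand", "start", "end")])
  if (!gene$contig %in% names(genome))
    .stopf("generate_candidates: unknown contig %s", gene$contig)
  if (gene$start < 0L || gene$end > nchar(genome[[gene$contig]]))
    .stopf("generate_candidates: gene %s outside genome", gene$gene_id)
  L <- gene$end - gene$start
  if (L < params$min_len) return(.empty_candidates())
  coding <- .gene_coding_sequence(gene, genome)

  grid <- do.call(rbind, lapply(params$min_len:min(params$max_len, L), function(l) {
    data.frame(tx_start = 0:(L - l), length = l)
  }))
  seqs <- substring(coding, grid$tx_start + 1L, grid$tx_start + grid$length)
  keep <- !grepl("N", seqs, fixed = TRUE)
  grid <- grid[keep, , drop = FALSE]
  seqs <- seqs[keep]
  if (nrow(grid) == 0L) return(.empty_candidates())
  tms <- melting_temperature(seqs)
  ok <- tms >= params$tm_min & tms <= params$tm_max
  if (!any(ok)) return(.empty_candidates())
  grid <- grid[ok, , drop = FALSE]
  out <- data.frame(
    gene_id = gene$gene_id,
    contig = gene$contig,
    target_strand = gene$strand,
    anneal_start = if (gene$strand == "+") gene$start + grid$tx_start
                   else gene$end - grid$tx_start - grid$length,
    anneal_end = if (gene$strand == "+") gene$start + grid$tx_start + grid$length
                 else gene$end - grid$tx_start,
    tx_start = grid$tx_start,
    length = grid$length,
    sequence = seqs[ok],
    tm = tms[ok],
    penalty = abs(tms[ok] - params$tm_opt) + 0.5 * abs(grid$length - params$opt_len),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$tx_start, out$penalty, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  w <- substring(s, 1:(n - k + 1L), k:n)
  w[!grepl("N", w, fixed = TRUE)]
}

.rrna_word_set <- function(rrna_regions, genome, k) {
  if (is.null(rrna_regions) || nrow(rrna_regions) == 0L) return(character(0))
  words <- lapply(seq_len(nrow(rrna_regions)), function(i) {
    r <- rrna_regions[i, ]
    s <- substr(genome[[r$contig]], r$start + 1L, r$end)
    c(.kmers(s, k), .kmers(revcomp(s), k))
  })
  unique(unlist(words))
}

#' Remove candidates sharing a word with rRNA
#'
#' A candidate is removed if and only if any of its substrings of length
#' `rrna_word` occurs exactly (0 mismatches) in any rRNA region sequence or
#' its reverse complement; all other candidates pass unchanged. The filter
#' is idempotent.
#'
#' @param candidates candidate data.frame from [generate_candidates()].
#' @param rrna_regions gene models of rRNA regions (may be empty).
#' @param genome reference genome.
#' @param params a [design_params()] object (supplies `rrna_word`).
#' @return the surviving candidates, order preserved.
#' @export
filter_rrna_words <- function(candidates, rrna_regions, genome,
                              params = design_params()) {
  if (nrow(candidates) == 0L) return(candidates)
  words <- .rrna_word_set(rrna_regions, genome, params$rrna_word)
  if (length(words) == 0L) return(candidates)
  k <- params$rrna_word
  seqs <- candidates$sequence
  n_off <- nchar(seqs) - k + 1L
  hit <- rep(FALSE, length(seqs))
  for (j in seq_len(max(0L, max(n_off)))) {
    hit <- hit | (n_off >= j & substring(seqs, j, j + k - 1L) %in% words)
  }
  out <- candidates[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select a spaced primer set by a greedy 5'->3' scan
#'
#' Candidates are processed per gene in transcript 5'->3' order. Walking
#' along the transcript, a candidate is admitted when its 5' end lies at
#' least `min_spacing` nt downstream of the 3' end of the last admitted
#' primer (the first admitted primer is unconstrained); among candidates at
#' the same 5' position the lowest penalty wins, ties broken by the
#' lexicographically smallest sequence. The scan yields a maximal set: no
#' rejected candidate can be added without violating spacing.
#'
#' @param candidates candidate data.frame (one or more genes).
#' @param params a [design_params()] object.
#' @param pool_id label for the resulting pool.
#' @return an object of class `primer_pool`: list with `primers` (selected
#'   candidates plus `primer_id`, `anneal_coord` and, after
#'   [append_adapter()], `oligo`), `pool_id` and `adapter`.
#' @export
select_spaced <- function(candidates, params = design_params(),
                          pool_id = "pool1") {
  pick <- .empty_candidates()
  if (nrow(candidates) > 0L) {
    for (g in unique(candidates$gene_id)) {
      cand <- candidates[candidates$gene_id == g, , drop = FALSE]
      cand <- cand[order(cand$tx_start, cand$penalty, cand$sequence), , drop = FALSE]
      last_tx3 <- NULL
      for (i in seq_len(nrow(cand))) {
        tx5 <- cand$tx_start[i]
        if (is.null(last_tx3) || tx5 - last_tx3 >= params$min_spacing) {
          pick <- rbind(pick, cand[i, , drop = FALSE])
          last_tx3 <- tx5 + cand$length[i] - 1L
        }
      }
    }
  }
  rownames(pick) <- NULL
  if (nrow(pick) > 0L) {
    pick$primer_id <- paste0(pick$gene_id, "_p",
                             stats::ave(seq_len(nrow(pick)), pick$gene_id,
                                        FUN = seq_along))
    # coordinate a second-strand read's adjusted 5' position must match
    pick$anneal_coord <- ifelse(pick$target_strand == "+",
                                pick$anneal_start, pick$anneal_end)
    pick$oligo <- NA_character_
  } else {
    pick$primer_id <- character(0)
    pick$anneal_coord <- integer(0)
    pick$oligo <- character(0)
  }
  structure(list(primers = pick, pool_id = pool_id, adapter = params$adapter),
            class = "primer_pool")
}

#' Append the common adapter to all pool primers
#'
#' Sets each primer's synthesis oligo to `adapter + primer sequence`; primer
#' fields are untouched.
#'
#' @param pool a `primer_pool`.
#' @param params a [design_params()] object (supplies the adapter).
#' @return the pool with the `oligo` column filled in.
#' @export
append_adapter <- function(pool, params = design_params()) {
  pool$adapter <- params$adapter
  pool$primers$oligo <- paste0(params$adapter, pool$primers$sequence)
  pool
}

#' Design a complete primer pool
#'
#' Convenience pipeline: for each target gene, enumerate candidates
#' ([generate_candidates()]), drop rRNA-homologous ones
#' ([filter_rrna_words()]), thin by spacing ([select_spaced()]) and append
#' the adapter ([append_adapter()]). rRNA regions default to the
#' `feature_class == "rRNA"` annotations.
#'
#' @param genome reference genome.
#' @param genes gene model data.frame.
#' @param targets character vector of gene ids to design against (default:
#'   all non-rRNA genes).
#' @param params a [design_params()] object.
#' @param pool_id label for the pool.
#' @return a `primer_pool`.
#' @export
design_primer_pool <- function(genome, genes, targets = NULL,
                               params = design_params(), pool_id = "pool1") {
  validate_gene_models(genes, genome)
  rrna <- genes[genes$feature_class == "rRNA", , drop = FALSE]
  if (is.null(targets)) targets <- genes$gene_id[genes$feature_class != "rRNA"]
  missing <- setdiff(targets, genes$gene_id)
  if (length(missing)) .stopf("unknown target gene: %s", missing[1L])
  cands <- lapply(targets, function(g) {
    generate_candidates(genes[genes$gene_id == g, ], genome, params)
  })
  cands <- do.call(rbind, c(list(.empty_candidates()), cands))
  cands <- filter_rrna_words(cands, rrna, genome, params)
  append_adapter(select_spaced(cands, params, pool_id), params)
}

#' Independently validate a primer pool
#'
#' Re-derives every pool invariant from raw sequence and coordinates rather
#' than trusting the design pipeline: oligos must be `adapter + primer`;
#' each primer sequence must equal the genome subsequence on the coding
#' strand of its gene; lengths and Tm (recomputed) must lie in the design
#' windows; per gene, consecutive selected primers must respect
#' `min_spacing` from 3' end to next 5' end; and no primer may share an
#' exact `rrna_word`-mer with any rRNA region on either strand (checked by
#' direct substring scan).
#'
#' @param pool a `primer_pool`.
#' @param genome reference genome.
#' @param genes gene model data.frame (source of gene bounds and rRNA
#'   regions).
#' @param params a [design_params()] object.
#' @return `TRUE`, invisibly, if all invariants hold; otherwise an error
#'   naming the first violated invariant.
#' @export
validate_primer_pool <- function(pool, genome, genes, params = design_params()) {
  p <- pool$primers
  if (nrow(p) == 0L) return(invisible(TRUE))
  if (any(is.na(p$oligo)) ||
      any(p$oligo != paste0(params$adapter, p$sequence)))
    .stopf("pool invariant violated: oligo != adapter + primer")
  if (any(nchar(p$sequence) < params$min_len | nchar(p$sequence) > params$max_len))
    .stopf("pool invariant violated: primer length outside [min_len, max_len]")
  for (i in seq_len(nrow(p))) {
    g <- genes[genes$gene_id == p$gene_id[i], ]
    if (nrow(g) != 1L) .stopf("pool primer %s has no gene model", p$primer_id[i])
    gseq <- substr(genome[[p$contig[i]]], p$anneal_start[i] + 1L, p$anneal_end[i])
    if (p$target_strand[i] == "-") gseq <- revcomp(gseq)
    if (gseq != p$sequence[i])
      .stopf("pool invariant violated: primer %s does not match the coding strand",
             p$primer_id[i])
  }
  tm <- melting_temperature(p$sequence)
  if (any(tm < params$tm_min - 1e-9 | tm > params$tm_max + 1e-9))
    .stopf("pool invariant violated: Tm outside [tm_min, tm_max]")
  for (g in unique(p$gene_id)) {
    gm <- genes[genes$gene_id == g, ]
    pg <- p[p$gene_id == g, , drop = FALSE]
    tx5 <- ifelse(gm$strand == "+", pg$anneal_start - gm$start,
                  gm$end - pg$anneal_end)
    tx3 <- tx5 + nchar(pg$sequence) - 1L
    ord <- order(tx5)
    if (length(ord) > 1L) {
      gaps <- tx5[ord][-1L] - tx3[ord][-length(ord)]
      if (any(gaps < params$min_spacing))
        .stopf("pool invariant violated: spacing < %d nt within gene %s",
               params$min_spacing, g)
    }
  }
  rrna <- genes[genes$feature_class == "rRNA", , drop = FALSE]
  if (nrow(rrna) > 0L) {
    rseqs <- vapply(seq_len(nrow(rrna)), function(i) {
      substr(genome[[rrna$contig[i]]], rrna$start[i] + 1L, rrna$end[i])
    }, character(1))
    rseqs <- c(rseqs, revcomp(rseqs))
    for (i in seq_len(nrow(p))) {
      for (w in .kmers(p$sequence[i], params$rrna_word)) {
        if (any(grepl(w, rseqs, fixed = TRUE)))
          .stopf("pool invariant violated: primer %s shares an %d-mer with rRNA",
                 p$primer_id[i], params$rrna_word)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.primer_pool <- function(x, ...) {
  p <- x$primers
  cat(sprintf("Primer pool '%s': %d primers across %d gene(s)\n",
              x$pool_id, nrow(p), length(unique(p$gene_id))))
  if (nrow(p) > 0L) {
    cat(sprintf("  adapter: %s\n", x$adapter))
    cat(sprintf("  Tm range: %.1f-%.1f C; lengths %d-%d nt\n",
                min(p$tm), max(p$tm), min(nchar(p$sequence)),
                max(nchar(p$sequence))))
  }
  invisible(x)
}

#' Write a primer pool manifest and oligo FASTA
#'
#' The manifest TSV has one row per selected primer (pool, gene, genomic
#' annealing coordinates, primer and full synthesis oligo sequence, Tm,
#' penalty); the optional FASTA holds the synthesis oligos.
#'
#' @param pool a `primer_pool`.
#' @param manifest_path output TSV path.
#' @param fasta_path optional output FASTA path for the oligos.
#' @return `manifest_path`, invisibly.
#' @export
write_primer_manifest <- function(pool, manifest_path, fasta_path = NULL) {
  p <- pool$primers
  man <- data.frame(pool_id = pool$pool_id, primer_id = p$primer_id,
                    gene_id = p$gene_id, contig = p$contig,
                    strand = p$target_strand, anneal_start = p$anneal_start,
                    anneal_end = p$anneal_end, primer_seq = p$sequence,
                    oligo_seq = p$oligo, tm = p$tm, penalty = p$penalty,
                    stringsAsFactors = FALSE)
  write.table(man, manifest_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_path) && nrow(p) > 0L) {
    write_fasta(setNames(p$oligo, p$primer_id), fasta_path)
  }
  invisible(manifest_path)
}
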