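# Read preprocessing: poly(A)-tail trimming, exhaustive best-stratum
# mapping, and the reverse-strand 5' position adjustment.

#' Poly(A) trimming parameters
#'
#' Defaults mirror 3'-adapter trimming with a 20-A adapter, a minimum
#' overlap of 10 nt and an error rate of 0.1.
#'
#' @param tail_adapter adapter sequence searched at the read 3' end
#'   (default 20 A's).
#' @param min_overlap minimum matched adapter length (nt).
#' @param max_error_rate maximum fraction of errors within the matched
#'   adapter bases.
#' @return an object of class `trim_params`.
#' @export
trim_params <- function(tail_adapter = strrep("A", 20L), min_overlap = 10L,
                        max_error_rate = 0.1) {
  p <- list(tail_adapter = toupper(tail_adapter),
            min_overlap = as.integer(min_overlap),
            max_error_rate = max_error_rate)
  if (p$min_overlap < 1L || p$min_overlap > nchar(p$tail_adapter))
    .stopf("trim_params: need 1 <= min_overlap <= length(tail_adapter)")
  if (p$max_error_rate < 0 || p$max_error_rate >= 0.5)
    .stopf("trim_params: need 0 <= max_error_rate < 0.5")
  class(p) <- "trim_params"
  p
}

#' Trim poly(A) tails with 3'-adapter semantics
#'
#' Finds the best occurrence of `tail_adapter` in each read: either a full
#' internal match or a partial match overlapping the read's 3' end by at
#' least `min_overlap` bases, allowing at most
#' `floor(max_error_rate * matched length)` mismatches. The read is trimmed
#' from the match start to its end (qualities in register); reads with no
#' qualifying match are returned unchanged. Among qualifying placements the
#' one with fewest errors wins, then the longest match, then the leftmost
#' start. Trimming never lengthens a read and is idempotent.
#'
#' @param reads a read data.frame (columns `sequence` and optionally
#'   `quality`; see [read_fastq()]) or a plain character vector.
#' @param params a [trim_params()] object.
#' @return object of the same shape as `reads` with trimmed sequences
#'   (and qualities).
#' @export
trim_polya <- function(reads, params = trim_params()) {
  plain <- is.character(reads)
  seqs <- if (plain) toupper(reads) else toupper(reads$sequence)
  cut <- .trim_polya_cpp(seqs, params$tail_adapter, params$min_overlap,
                         params$max_error_rate)
  trimmed <- ifelse(cut >= 0L, substr(seqs, 1L, cut), seqs)
  if (plain) return(trimmed)
  reads$sequence <- trimmed
  if (!is.null(reads$quality)) {
    reads$quality <- ifelse(cut >= 0L, substr(reads$quality, 1L, cut),
                            reads$quality)
  }
  reads
}

.as_read_frame <- function(reads) {
  if (is.character(reads)) {
    reads <- data.frame(
      read_id = if (!is.null(names(reads))) names(reads)
                else sprintf("read%d", seq_along(reads)),
      sample_id = "sample1",
      sequence = unname(reads),
      stringsAsFactors = FALSE
    )
  }
  reads$sequence <- toupper(reads$sequence)
  reads
}

# Exact-match fast path: hash lookup of reads against all genome substrings
# of the same length (both strands), honouring the mapper's tie order.
# Only worthwhile when many reads share one length on a small genome.
.exact_match_bulk <- function(seqs, contigs) {
  n <- length(seqs)
  res <- data.frame(contig = rep(NA_integer_, n), pos = rep(NA_integer_, n),
                    strand = rep(NA_integer_, n))
  lens <- nchar(seqs)
  clen <- nchar(contigs)
  total <- sum(clen)
  if (total > 5e5) return(res)
  eligible <- !grepl("N", seqs, fixed = TRUE)
  for (L in unique(lens)) {
    if (L < 1L) next
    idx <- which(lens == L & eligible)
    if (length(idx) < 500L) next
    tab_f <- character(0); tab_r <- character(0)
    key_contig <- integer(0); key_pos <- integer(0)
    for (ci in seq_along(contigs)) {
      np <- clen[ci] - L + 1L
      if (np < 1L) next
      subs <- substring(contigs[ci], 1:np, L:clen[ci])
      tab_f <- c(tab_f, subs)
      tab_r <- c(tab_r, revcomp(subs))
      key_contig <- c(key_contig, rep.int(ci, np))
      key_pos <- c(key_pos, 0:(np - 1L))
    }
    if (length(tab_f) == 0L) next
    mf <- match(seqs[idx], tab_f)  # first occurrence == smallest (contig, pos)
    mr <- match(seqs[idx], tab_r)
    use_f <- !is.na(mf) & (is.na(mr) | mf <= mr)  # forward before reverse
    use_r <- !is.na(mr) & !use_f
    hit <- ifelse(use_f, mf, ifelse(use_r, mr, NA_integer_))
    got <- !is.na(hit)
    res$contig[idx[got]] <- key_contig[hit[got]]
    res$pos[idx[got]] <- key_pos[hit[got]]
    res$strand[idx[got]] <- ifelse(use_f[got], 0L, 1L)
  }
  res
}

#' Map reads by exhaustive best-stratum placement
#'
#' Considers every end-to-end placement of each read on both strands of
#' every contig with at most `max_mismatches` mismatches (`N` never
#' matches), and reports exactly one alignment from the lowest-mismatch
#' stratum; ties are broken deterministically by contig id, then
#' coordinate, then forward before reverse strand. Reads with no qualifying
#' placement are returned unmapped. Intended for fixture-scale genomes
#' (up to a few megabases); external SAM/bowtie alignments are the
#' supported path for real-scale data ([read_alignments()]). Exact matches
#' are resolved through a hash fast path when many reads share a length;
#' everything else goes through the exhaustive compiled scan.
#'
#' @param reads read data.frame (see [read_fastq()]) or character vector.
#' @param genome reference genome (named character vector).
#' @param max_mismatches maximum mismatches for a reportable placement.
#' @return list with `alignments` (alignment data.frame) and `unmapped`
#'   (the unplaceable reads).
#' @export
map_reads <- function(reads, genome, max_mismatches = 2L) {
  validate_genome(genome)
  reads <- .as_read_frame(reads)
  ord <- order(names(genome))
  contigs <- unname(genome[ord])
  contig_ids <- names(genome)[ord]
  n <- nrow(reads)
  if (n == 0L) return(list(alignments = .empty_alignments(), unmapped = reads))

  hit <- .exact_match_bulk(reads$sequence, contigs)
  todo <- which(is.na(hit$contig))
  mm <- integer(n)
  if (length(todo)) {
    res <- .map_reads_cpp(reads$sequence[todo], contigs, as.integer(max_mismatches))
    hit$contig[todo] <- res$contig
    hit$pos[todo] <- res$pos
    hit$strand[todo] <- res$strand
    mm[todo] <- ifelse(is.na(res$mismatches), 0L, res$mismatches)
  }
  mapped <- !is.na(hit$contig)
  aln <- data.frame(
    read_id = reads$read_id[mapped],
    sample_id = reads$sample_id[mapped],
    contig = contig_ids[hit$contig[mapped]],
    strand = c("+", "-")[hit$strand[mapped] + 1L],
    pos = hit$pos[mapped],
    read_length = nchar(reads$sequence[mapped]),
    mismatches = mm[mapped],
    stringsAsFactors = FALSE
  )
  rownames(aln) <- NULL
  unmapped <- reads[!mapped, , drop = FALSE]
  rownames(unmapped) <- NULL
  list(alignments = aln, unmapped = unmapped)
}

#' Adjust 5' positions for reverse-strand alignments
#'
#' Forward-strand reads keep their mapped position; reverse-strand reads
#' get `adj_pos = pos + read_length`, so that `adj_pos` marks the read's 5'
#' end in a single convention usable for gene counting and primer
#' matching. No records are dropped or duplicated and no other field is
#' altered.
#'
#' @param alignments alignment data.frame (see [read_alignments()]).
#' @return the same data.frame with an `adj_pos` column appended.
#' @export
adjust_positions <- function(alignments) {
  alignments$adj_pos <- ifelse(alignments$strand == "-",
                               alignments$pos + alignments$read_length,
                               alignments$pos)
  alignments
}
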