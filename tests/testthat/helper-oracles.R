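# Independent oracles and fixture builders. Everything here is written as
# plainly as possible and kept structurally independent of the package
# implementation it checks.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(s, "", fixed = TRUE),
                function(b) paste(rev(b), collapse = ""), character(1)))
}

# --- nearest-neighbor Tm oracle: explicit 16-entry tables, plain loop -----
ORACLE_NN_DH <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
                  CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
                  GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
                  TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
ORACLE_NN_DS <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
                  CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
                  GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
                  TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)

oracle_tm <- function(seq, na_molar = 0.05, oligo_molar = 250e-9) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  dh <- 0; ds <- 0
  for (i in seq_len(n - 1)) {
    key <- paste0(b[i], b[i + 1])
    dh <- dh + ORACLE_NN_DH[[key]]
    ds <- ds + ORACLE_NN_DS[[key]]
  }
  for (t in c(b[1], b[n])) {
    if (t == "G" || t == "C") { dh <- dh + 0.1; ds <- ds - 2.8 }
    else                      { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(na_molar)
  x <- if (seq == rc_chr(seq)) 1 else 4
  1000 * dh / (ds + 1.9872 * log(oligo_molar / x)) - 273.15
}

# --- exhaustive mapper oracle ---------------------------------------------
# Scores every end-to-end placement on both strands of every contig by raw
# byte comparison, keeps the lowest-mismatch stratum, and breaks ties by
# (contig id, coordinate, forward before reverse).
oracle_map_read <- function(seq, genome, max_mm = 2L) {
  L <- nchar(seq)
  rawN <- charToRaw("N")[1]
  hits <- list()
  for (cid in sort(names(genome))) {
    g <- charToRaw(genome[[cid]])
    n <- length(g)
    if (L > n) next
    npos <- n - L + 1L
    for (sr in c("+", "-")) {
      q <- charToRaw(if (sr == "+") seq else rc_chr(seq))
      mm <- integer(npos)
      for (j in seq_len(L)) {
        gj <- g[j:(j + npos - 1L)]
        mm <- mm + as.integer(gj != q[j] | gj == rawN | q[j] == rawN)
      }
      ok <- which(mm <= max_mm)
      if (length(ok))
        hits[[length(hits) + 1L]] <- data.frame(
          contig = cid, pos = ok - 1L, strand = sr, mismatches = mm[ok],
          stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(NULL)
  h <- do.call(rbind, hits)
  h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
  h <- h[order(h$contig, h$pos, h$strand), , drop = FALSE]  # "+" < "-"
  h[1L, ]
}

# --- exhaustive adapter-placement trimming oracle -------------------------
# Scores every adapter placement; qualifying placements need error count
# <= floor(rate * matched length) and (for partial, suffix-overlapping
# matches) matched length >= min_overlap. Picks minimal errors, then the
# longest match, then the leftmost start, and trims from there.
oracle_trim <- function(seq, adapter = strrep("A", 20), min_overlap = 10,
                        rate = 0.1) {
  sb <- strsplit(seq, "", fixed = TRUE)[[1]]
  ab <- strsplit(adapter, "", fixed = TRUE)[[1]]
  L <- length(sb); alen <- length(ab)
  best <- NULL
  for (i in seq_len(L)) {
    m <- min(alen, L - i + 1L)
    if (m < min_overlap) next
    w <- sb[i:(i + m - 1L)]
    a <- ab[1:m]
    err <- sum(w != a | w == "N" | a == "N")
    if (err > floor(rate * m)) next
    if (is.null(best) || err < best$err || (err == best$err && m > best$m)) {
      best <- list(err = err, m = m, i = i)
    }
  }
  if (is.null(best)) seq else substr(seq, 1L, best$i - 1L)
}

# --- exhaustive primer-window oracle --------------------------------------
# Enumerates every window of each allowed length inside the coding-strand
# sequence and keeps those whose Tm (same model as the package exposes)
# falls in the design window.
oracle_candidate_windows <- function(gene, genome, params) {
  L <- gene$end - gene$start
  coding <- substr(genome[[gene$contig]], gene$start + 1L, gene$end)
  if (gene$strand == "-") coding <- rc_chr(coding)
  rows <- list()
  for (l in params$min_len:params$max_len) {
    if (l > L) next
    for (t in 0:(L - l)) {
      w <- substr(coding, t + 1L, t + l)
      if (grepl("N", w, fixed = TRUE)) next
      tm <- melting_temperature(w)
      if (tm >= params$tm_min && tm <= params$tm_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          tx_start = t, length = l, sequence = w, tm = tm,
          penalty = abs(tm - params$tm_opt) + 0.5 * abs(l - params$opt_len),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$tx_start, out$penalty, out$sequence), , drop = FALSE]
}

# brute-force: does this primer share any k-mer with an rRNA region
# (either strand)?
oracle_shares_rrna_word <- function(primer, rrna_seqs, k) {
  targets <- c(rrna_seqs, rc_chr(rrna_seqs))
  n <- nchar(primer)
  for (j in seq_len(n - k + 1L)) {
    w <- substr(primer, j, j + k - 1L)
    if (grepl("N", w, fixed = TRUE)) next
    if (any(grepl(w, targets, fixed = TRUE))) return(TRUE)
  }
  FALSE
}

# --- small fixture builders -----------------------------------------------
toy_genes <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], contig = r[[2]], strand = r[[3]],
               start = as.integer(r[[4]]), end = as.integer(r[[5]]),
               feature_class = r[[6]], stringsAsFactors = FALSE)
  }))
}

toy_alignments <- function(adj_pos, strand, contig = "chr1",
                           sample_id = "s1", read_length = 30L) {
  n <- length(adj_pos)
  data.frame(
    read_id = sprintf("r%03d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    contig = rep_len(contig, n),
    strand = rep_len(strand, n),
    pos = ifelse(rep_len(strand, n) == "-", adj_pos - read_length, adj_pos),
    read_length = rep_len(read_length, n),
    mismatches = rep_len(0L, n),
    adj_pos = as.integer(adj_pos),
    stringsAsFactors = FALSE
  )
}

toy_reads <- function(seqs, sample_id = "s1") {
  data.frame(read_id = sprintf("r%03d", seq_along(seqs)),
             sample_id = rep_len(sample_id, length(seqs)),
             sequence = seqs, quality = strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}

# expression table straight from a count matrix (features x samples)
table_from_counts <- function(counts, kind = "gene",
                              policy = "all_feature_reads") {
  tab <- tbamkit:::.new_expression_table(counts, kind, 100L, policy)
  compute_rpm(tab)
}
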