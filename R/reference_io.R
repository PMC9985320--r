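# Domain containers and file-boundary conversions.
#
# Internally, every coordinate is 0-based half-open on the forward strand of
# its contig. 1-based formats (GFF3, SAM) are converted exactly once, here.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character DNA (A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.check_dna_alphabet <- function(seqs, what) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    .stopf("%s %s contains characters outside {A,C,G,T,N}",
           what, names(seqs)[bad][1L] %||% which(bad)[1L])
  }
  invisible(TRUE)
}

#' Validate a reference genome
#'
#' A reference genome is a named character vector: contig id -> uppercase DNA
#' sequence over {A,C,G,T,N}. Contig ids must be unique and non-empty and
#' sequences non-empty.
#'
#' @param genome named character vector of contig sequences.
#' @return the genome, invisibly, if valid; otherwise an error.
#' @export
validate_genome <- function(genome) {
  if (!is.character(genome) || length(genome) == 0L)
    .stopf("genome must be a non-empty named character vector")
  ids <- names(genome)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    .stopf("all contigs must have non-empty ids")
  if (anyDuplicated(ids))
    .stopf("duplicated contig id: %s", ids[duplicated(ids)][1L])
  if (any(!nzchar(genome)))
    .stopf("contig %s has an empty sequence", ids[!nzchar(genome)][1L])
  .check_dna_alphabet(genome, "contig")
  invisible(genome)
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and RNA `U` is converted to `T`; the alphabet is
#' then restricted to {A,C,G,T,N}. Contig ids are the first whitespace token
#' of each header.
#'
#' @param path path to a FASTA file.
#' @return named character vector of contig sequences (a reference genome).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) .stopf("no records in FASTA file %s", path)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    .stopf("FASTA parse error at line %d of %s: expected '>' header",
           nonblank[1L], path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) .stopf("no records in FASTA file %s", path)
  seqs <- chartr("u", "t", toupper(as.character(x)))
  seqs <- chartr("U", "T", seqs)
  ids <- sub("\\s.*$", "", names(x))
  names(seqs) <- ids
  validate_genome(seqs)
  seqs
}

#' Write a reference genome to FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  validate_genome(genome)
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.feature_class_from_type <- function(type) {
  out <- rep("other", length(type))
  out[toupper(type) == "CDS"] <- "CDS"
  out[grepl("rRNA", type, ignore.case = TRUE)] <- "rRNA"
  out
}

#' Read gene models from GFF3 or BED
#'
#' Coordinates are normalised to 0-based half-open regardless of dialect
#' (GFF3 1-based inclusive is converted; BED passes through). Feature class
#' (`CDS`, `rRNA`, `other`) is taken from the GFF3 type column; for BED,
#' which has no type column, a name matching `rRNA`/`rrn` is classed as rRNA
#' and everything else as `other`. Records that are empty after conversion
#' (start >= end) or that lack a usable strand are rejected with a warning.
#'
#' @param path path to the annotation file.
#' @param dialect `"gff3"` or `"bed"`.
#' @param genome optional reference genome; when supplied, contig ids and
#'   bounds are checked against it.
#' @return data.frame with columns `gene_id`, `contig`, `strand`, `start`,
#'   `end`, `feature_class` (0-based half-open coordinates).
#' @export
read_annotations <- function(path, dialect = c("gff3", "bed"), genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "bed")
  md <- as.data.frame(gr)
  n <- nrow(md)
  if (n == 0L) {
    return(data.frame(gene_id = character(0), contig = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), feature_class = character(0),
                      stringsAsFactors = FALSE))
  }
  if (dialect == "gff3") {
    ids <- md$ID %||% rep(NA_character_, n)
    if ("Name" %in% names(md)) ids <- ifelse(is.na(ids), md$Name, ids)
    fc <- .feature_class_from_type(as.character(md$type))
  } else {
    ids <- md$name %||% rep(NA_character_, n)
    fc <- ifelse(grepl("rRNA|^rrn", ids %||% "", ignore.case = TRUE), "rRNA", "other")
    fc[is.na(ids)] <- "other"
  }
  ids[is.na(ids)] <- sprintf("feature_%d", which(is.na(ids)))
  genes <- data.frame(
    gene_id = as.character(ids),
    contig = as.character(md$seqnames),
    strand = as.character(md$strand),
    start = as.integer(md$start) - 1L,   # GRanges is 1-based inclusive
    end = as.integer(md$end),
    feature_class = fc,
    stringsAsFactors = FALSE
  )
  bad_coord <- genes$start >= genes$end
  if (any(bad_coord)) {
    .warnf("rejecting %d record(s) with start >= end after conversion (first: %s)",
           sum(bad_coord), genes$gene_id[bad_coord][1L])
    genes <- genes[!bad_coord, , drop = FALSE]
  }
  bad_strand <- !(genes$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    .warnf("rejecting %d record(s) without a '+'/'-' strand (first: %s)",
           sum(bad_strand), genes$gene_id[bad_strand][1L])
    genes <- genes[!bad_strand, , drop = FALSE]
  }
  rownames(genes) <- NULL
  validate_gene_models(genes, genome)
  genes
}

#' Validate gene models
#'
#' Checks coordinate sanity (0 <= start < end), unique gene ids, strand in
#' {+, -}, known feature classes and, when a genome is supplied, containment
#' within the named contigs.
#'
#' @param genes gene model data.frame (see [read_annotations()]).
#' @param genome optional reference genome to check contigs and bounds
#'   against.
#' @return `genes`, invisibly, if valid.
#' @export
validate_gene_models <- function(genes, genome = NULL) {
  need <- c("gene_id", "contig", "strand", "start", "end", "feature_class")
  if (!all(need %in% names(genes)))
    .stopf("gene models must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    .stopf("duplicated gene_id: %s", genes$gene_id[duplicated(genes$gene_id)][1L])
  if (any(!genes$strand %in% c("+", "-")))
    .stopf("gene strand must be '+' or '-'")
  if (any(genes$start < 0L) || any(genes$start >= genes$end))
    .stopf("gene coordinates must satisfy 0 <= start < end")
  if (any(!genes$feature_class %in% c("CDS", "rRNA", "other")))
    .stopf("feature_class must be one of CDS, rRNA, other")
  if (!is.null(genome)) {
    unknown <- setdiff(genes$contig, names(genome))
    if (length(unknown)) .stopf("unknown contig in annotations: %s", unknown[1L])
    len <- nchar(genome)[genes$contig]
    if (any(genes$end > len))
      .stopf("gene %s extends beyond its contig",
             genes$gene_id[genes$end > len][1L])
  }
  invisible(genes)
}

#' Write gene models to GFF3 or BED
#'
#' The inverse of [read_annotations()]: internal 0-based half-open
#' coordinates are converted back to the dialect's convention. GFF3 output
#' preserves the feature class in the type column; BED output keeps only the
#' interval, name, and strand.
#'
#' @param genes gene model data.frame.
#' @param path output path.
#' @param dialect `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(genes, path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  validate_gene_models(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  if (dialect == "gff3") {
    gr$type <- genes$feature_class
    gr$ID <- genes$gene_id
    gr$source <- "tbamkit"
    gr$phase <- ifelse(genes$feature_class == "CDS", 0L, NA_integer_)
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    gr$name <- genes$gene_id
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read demultiplexed reads from FASTQ
#'
#' Sample identity is carried per read: a header token `sample=<id>` wins;
#' otherwise the `sample_id` argument applies to the whole file; otherwise
#' the file basename (without extension) is used. Inputs are assumed to be
#' already demultiplexed (one sample per file or tagged headers); barcode
#' sequence handling is out of scope.
#'
#' @param path path to a FASTQ file.
#' @param sample_id optional sample label for all reads in the file.
#' @return data.frame with columns `read_id`, `sample_id`, `sequence`,
#'   `quality`.
#' @export
read_fastq <- function(path, sample_id = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  # suppressed: Biostrings warns about dropping its own metadata columns
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  m <- regexpr("sample=\\S+", headers)
  has_tok <- m > 0L
  default_sample <- sample_id %||% sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  samples <- rep(default_sample, length(x))
  samples[has_tok] <- sub("^sample=", "", regmatches(headers, m))
  data.frame(
    read_id = ids,
    sample_id = samples,
    sequence = as.character(x),
    quality = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write reads to FASTQ
#'
#' Sample identity is preserved as a `sample=<id>` header token so that a
#' round trip through [read_fastq()] reproduces the table. Missing qualities
#' are written as `I` (Phred 40).
#'
#' @param reads data.frame with columns `read_id`, `sample_id`, `sequence`
#'   and optionally `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality
  if (is.null(qual)) qual <- rep(NA_character_, nrow(reads))
  miss <- is.na(qual) | !nzchar(qual)
  qual[miss] <- vapply(nchar(reads$sequence[miss]),
                       function(n) strrep("I", n), character(1))
  if (any(nchar(qual) != nchar(reads$sequence)))
    .stopf("quality strings must match sequence lengths")
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(qual)
  )
  names(x) <- paste0(reads$read_id, " sample=", reads$sample_id)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = Biostrings::quality(x))
  invisible(path)
}

.empty_alignments <- function() {
  data.frame(read_id = character(0), sample_id = character(0),
             contig = character(0), strand = character(0),
             pos = integer(0), read_length = integer(0),
             mismatches = integer(0), stringsAsFactors = FALSE)
}

.validate_alignments <- function(aln, genome = NULL) {
  if (nrow(aln) == 0L) return(invisible(aln))
  if (any(aln$pos < 0L) || any(aln$read_length < 1L) || any(aln$mismatches < 0L))
    .stopf("alignment coordinates out of range")
  if (any(!aln$strand %in% c("+", "-"))) .stopf("alignment strand must be '+' or '-'")
  if (!is.null(genome)) {
    unknown <- setdiff(aln$contig, names(genome))
    if (length(unknown)) .stopf("alignment on unknown contig: %s", unknown[1L])
    len <- nchar(genome)[aln$contig]
    if (any(aln$pos + aln$read_length > len))
      .stopf("alignment beyond contig end (read %s)",
             aln$read_id[aln$pos + aln$read_length > len][1L])
  }
  invisible(aln)
}

.parse_sam <- function(lines, sample_id) {
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    .stopf("SAM parse error: line with %d fields (11 required)", min(nf))
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  mapped <- bitwAnd(flag, 4L) == 0L
  fields <- fields[mapped]
  if (length(fields) == 0L) return(.empty_alignments())
  flag <- flag[mapped]
  seqs <- vapply(fields, `[[`, "", 10L)
  if (any(seqs == "*"))
    .stopf("SAM records without a SEQ field are not supported")
  nm <- vapply(fields, function(f) {
    tags <- f[-(1:11)]
    hit <- grep("^NM:i:", tags, value = TRUE)
    if (length(hit)) as.integer(sub("^NM:i:", "", hit[1L])) else 0L
  }, integer(1))
  data.frame(
    read_id = vapply(fields, `[[`, "", 1L),
    sample_id = sample_id,
    contig = vapply(fields, `[[`, "", 3L),
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    pos = as.integer(vapply(fields, `[[`, "", 4L)) - 1L,  # SAM is 1-based
    read_length = nchar(seqs),
    mismatches = nm,
    stringsAsFactors = FALSE
  )
}

.parse_bowtie_legacy <- function(lines, sample_id) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L))
    .stopf("bowtie legacy parse error: line with %d fields (5 required)", min(nf))
  mm <- vapply(fields, function(f) {
    if (length(f) >= 8L && nzchar(f[[8L]]))
      length(strsplit(f[[8L]], ",", fixed = TRUE)[[1L]])
    else 0L
  }, integer(1))
  data.frame(
    read_id = vapply(fields, `[[`, "", 1L),
    sample_id = sample_id,
    contig = vapply(fields, `[[`, "", 3L),
    strand = vapply(fields, `[[`, "", 2L),
    pos = as.integer(vapply(fields, `[[`, "", 4L)),  # already 0-based
    read_length = nchar(vapply(fields, `[[`, "", 5L)),
    mismatches = mm,
    stringsAsFactors = FALSE
  )
}

#' Read alignments from SAM, bowtie legacy, or tbamkit TSV
#'
#' Unmapped SAM records (flag bit 4) are skipped. SAM `POS` (1-based) is
#' converted to the internal 0-based convention; bowtie legacy offsets are
#' already 0-based and pass through. Mismatch counts come from the `NM` tag
#' (SAM) or the mismatch-descriptor column (bowtie legacy), defaulting to 0
#' when absent.
#'
#' @param path path to the alignment file.
#' @param dialect `"sam"`, `"bowtie_legacy"`, or `"tsv"` (the package's own
#'   tab format, which round-trips [write_alignments()]).
#' @param genome optional reference genome; when supplied, coordinates are
#'   checked against contig bounds.
#' @param sample_id sample label for dialects that cannot carry one
#'   (defaults to the file basename).
#' @return alignment data.frame with columns `read_id`, `sample_id`,
#'   `contig`, `strand`, `pos`, `read_length`, `mismatches`.
#' @export
read_alignments <- function(path, dialect = c("sam", "bowtie_legacy", "tsv"),
                            genome = NULL, sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  if (dialect == "tsv") {
    aln <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("read_id", "sample_id", "contig", "strand", "pos",
              "read_length", "mismatches")
    if (!all(need %in% names(aln)))
      .stopf("alignment TSV must have columns: %s", paste(need, collapse = ", "))
    aln <- aln[, need]
    aln$pos <- as.integer(aln$pos)
    aln$read_length <- as.integer(aln$read_length)
    aln$mismatches <- as.integer(aln$mismatches)
  } else {
    lines <- readLines(path, warn = FALSE)
    aln <- if (dialect == "sam") .parse_sam(lines, sample_id)
           else .parse_bowtie_legacy(lines, sample_id)
  }
  .validate_alignments(aln, genome)
  aln
}

#' Write alignments to the tbamkit TSV format
#'
#' Columns: `read_id`, `sample_id`, `contig`, `strand`, `pos`,
#' `read_length`, `mismatches`, plus `adj_pos` if present. Reading the file
#' back with `read_alignments(dialect = "tsv")` reproduces the table.
#'
#' @param aln alignment data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  cols <- c("read_id", "sample_id", "contig", "strand", "pos",
            "read_length", "mismatches")
  if ("adj_pos" %in% names(aln)) cols <- c(cols, "adj_pos")
  write.table(aln[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
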