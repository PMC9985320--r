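# Barcode-switching estimation and sequencing-depth redistribution
# planning.

.new_switch_estimate <- function(rate, num, den, n_target, method) {
  structure(list(rate = rate, numerator_reads = num, denominator_reads = den,
                 n_target_samples = n_target, method = method),
            class = "switch_estimate")
}

#' @export
print.switch_estimate <- function(x, ...) {
  cat(sprintf("Barcode-switching estimate (%s): %.4g (%.3g%%)\n",
              x$method, x$rate, 100 * x$rate))
  cat(sprintf("  %g / %g reads, %d target-containing sample(s)\n",
              x$numerator_reads, x$denominator_reads, x$n_target_samples))
  invisible(x)
}

#' Barcode-switching rate from a knockout design
#'
#' In a pool where one sample comes from a strain deleted for a target
#' gene and the remaining samples carry wildtype levels, reads of that gene
#' appearing under the knockout barcode must have switched in from other
#' samples. The per-pair switching rate is the fraction of reads mapped to
#' the target (gene CDS or targeting primer) in the knockout versus the
#' wildtype sample, divided by the number of target-gene-containing samples
#' in the pool. Inputs are counts at matched depth; normalise per million
#' upstream if sample depths differ.
#'
#' @param ko_reads target-feature reads in the knockout sample.
#' @param wt_reads target-feature reads in a wildtype sample (> 0).
#' @param n_target_samples number of samples in the pool carrying the
#'   target gene (>= 1).
#' @return a `switch_estimate` with
#'   `rate = (ko_reads / wt_reads) / n_target_samples`.
#' @examples
#' knockout_switch_rate(3, 153, 14)  # ~0.0014, i.e. < 0.15%
#' @export
knockout_switch_rate <- function(ko_reads, wt_reads, n_target_samples) {
  if (wt_reads <= 0) .stopf("knockout_switch_rate: wt_reads must be > 0")
  if (n_target_samples < 1L)
    .stopf("knockout_switch_rate: n_target_samples must be >= 1")
  if (ko_reads < 0) .stopf("knockout_switch_rate: ko_reads must be >= 0")
  rate <- (ko_reads / wt_reads) / n_target_samples
  .new_switch_estimate(rate, ko_reads, wt_reads, as.integer(n_target_samples),
                       "knockout")
}

#' Barcode-switching rate from a mixed-species pool
#'
#' When samples from two species are pooled, reads carrying one species'
#' barcode but mapping to the other species' genome must have switched.
#' The rate is the number of foreign-barcode reads mapping to the genome
#' divided by the total uniquely mapped reads of that genome in the pool.
#'
#' @param foreign_barcode_reads reads with the other species' barcode
#'   mapping to this genome.
#' @param total_unique_reads total uniquely mapped reads of this genome in
#'   the pool (> 0).
#' @return a `switch_estimate` with `rate = foreign / total`.
#' @examples
#' cross_species_switch_rate(157509, 11936187)  # ~1.3%
#' @export
cross_species_switch_rate <- function(foreign_barcode_reads, total_unique_reads) {
  if (total_unique_reads <= 0)
    .stopf("cross_species_switch_rate: total_unique_reads must be > 0")
  if (foreign_barcode_reads < 0)
    .stopf("cross_species_switch_rate: foreign_barcode_reads must be >= 0")
  .new_switch_estimate(foreign_barcode_reads / total_unique_reads,
                       foreign_barcode_reads, total_unique_reads, 1L,
                       "mixed_species")
}

#' Reads required to cover all genes in one pool
#'
#' Given per-gene read counts at some reference depth (sorted descending),
#' the depth at which the least abundant gene reaches `min_reads` reads is
#' found by scaling: divide `min_reads` by the last gene's count and
#' multiply the summed counts by that factor, rounding up.
#'
#' @param counts positive per-gene read counts, sorted descending.
#' @param min_reads required reads for every gene (default 100).
#' @return required total reads (integer-valued numeric).
#' @export
required_reads_single_pool <- function(counts, min_reads = 100L) {
  if (length(counts) == 0L) return(0)
  if (any(counts <= 0))
    .stopf("required_reads_single_pool: zero-count gene cannot be covered at any depth")
  if (is.unsorted(rev(counts)))
    .stopf("required_reads_single_pool: counts must be sorted descending")
  ceiling(min_reads / counts[length(counts)] * sum(counts))
}

#' Plan sequencing-depth redistribution across abundance tiers
#'
#' Partitions the descending-sorted genes into `n_groups` consecutive
#' blocks of (near-)equal size (any remainder goes to the earliest groups),
#' applies the single-pool depth formula within each block, and sums. When
#' each block is captured by its own primer pool and the pools re-mixed,
#' abundant genes no longer force redundant sequencing of rare ones; the
#' reported `fold_reduction` is the single-pool requirement divided by the
#' tiered total and is always >= 1 for descending-ordered grouping.
#'
#' @param counts positive per-gene read counts; sorted descending
#'   internally (ties keep input order).
#' @param n_groups number of tiers (1 <= n_groups <= number of genes).
#' @param min_reads required reads for every gene (default 100).
#' @param gene_ids optional gene labels (same length as `counts`).
#' @return object of class `redistribution_plan`: `groups` (data.frame
#'   with `group`, `gene_id`, `count`), `per_group_required`,
#'   `total_required`, `single_pool_required`, `fold_reduction`,
#'   `min_reads_per_gene`.
#' @export
plan_redistribution <- function(counts, n_groups, min_reads = 100L,
                                gene_ids = NULL) {
  n <- length(counts)
  if (n_groups < 1L) .stopf("plan_redistribution: n_groups must be >= 1")
  if (n_groups > n)
    .stopf("plan_redistribution: n_groups (%d) exceeds number of genes (%d)",
           n_groups, n)
  if (any(counts <= 0))
    .stopf("plan_redistribution: zero-count gene cannot be covered at any depth")
  gene_ids <- gene_ids %||% sprintf("gene%04d", seq_len(n))
  ord <- order(-counts)
  counts <- counts[ord]
  gene_ids <- gene_ids[ord]
  sizes <- rep(n %/% n_groups, n_groups)
  extra <- n %% n_groups
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  group <- rep(seq_len(n_groups), times = sizes)
  per_group <- vapply(seq_len(n_groups), function(g) {
    required_reads_single_pool(counts[group == g], min_reads)
  }, numeric(1))
  total <- sum(per_group)
  single <- required_reads_single_pool(counts, min_reads)
  structure(list(
    groups = data.frame(group = group, gene_id = gene_ids, count = counts,
                        stringsAsFactors = FALSE),
    per_group_required = per_group,
    total_required = total,
    single_pool_required = single,
    fold_reduction = single / total,
    min_reads_per_gene = as.integer(min_reads)
  ), class = "redistribution_plan")
}

#' @export
print.redistribution_plan <- function(x, ...) {
  k <- length(x$per_group_required)
  cat(sprintf("Redistribution plan: %d genes in %d group(s), >= %d reads/gene\n",
              nrow(x$groups), k, x$min_reads_per_gene))
  for (g in seq_len(k)) {
    cnt <- x$groups$count[x$groups$group == g]
    cat(sprintf("  group %d: %d genes (counts %g..%g) -> %s reads\n",
                g, length(cnt), max(cnt), min(cnt),
                format(x$per_group_required[g], big.mark = ",")))
  }
  cat(sprintf("  tiered total: %s reads; single pool: %s reads; fold reduction: %.1fx\n",
              format(x$total_required, big.mark = ","),
              format(x$single_pool_required, big.mark = ","),
              x$fold_reduction))
  invisible(x)
}
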