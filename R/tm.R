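# Nearest-neighbor duplex melting temperature.
#
# Unified nearest-neighbor parameter set (10 Watson-Crick stacks plus
# terminal initiation terms), with entropic salt correction
# 0.368 * (N-1) * ln[Na+]. Conditions are fixed: 50 mM monovalent cation,
# 250 nM total oligo. Changing them is an explicit argument, never silent.

# dH in kcal/mol, dS in cal/(mol K); keys are the 5'->3' top-strand stack.
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)

.nn_tables <- local({
  dh <- .NN_DH
  ds <- .NN_DS
  rc2 <- function(d) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(d, "", fixed = TRUE)[[1L]]), collapse = ""))
  bases <- c("A", "C", "G", "T")
  for (a in bases) for (b in bases) {
    d <- paste0(a, b)
    if (!d %in% names(dh)) {
      dh[d] <- dh[rc2(d)]
      ds[d] <- ds[rc2(d)]
    }
  }
  list(dh = dh, ds = ds)
})

.R_GAS <- 1.9872  # cal / (mol K)

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of a DNA oligo against its perfect complement,
#' from a unified nearest-neighbor thermodynamic sum: stacking
#' enthalpies/entropies over all dinucleotide steps plus terminal duplex
#' initiation terms, with the entropic salt correction
#' `0.368 * (N - 1) * ln[Na+]`. Tm (Kelvin) is
#' `1000 * dH / (dS + R * ln(CT / x))` with `x = 4` for
#' non-self-complementary sequences and `x = 1` for self-complementary ones;
#' the result is returned in degrees Celsius. Deterministic; `N` bases are
#' rejected.
#'
#' @param sequence character vector of DNA sequences (length >= 8 each,
#'   alphabet {A,C,G,T}).
#' @param na_molar monovalent cation concentration in mol/L (default 0.05).
#' @param oligo_molar total oligo concentration in mol/L (default 250e-9).
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' melting_temperature("TCGATTGCCAAGTCCGGTTA")
#' @export
melting_temperature <- function(sequence, na_molar = 0.05, oligo_molar = 250e-9) {
  if (length(sequence) == 0L) return(numeric(0))
  sequence <- toupper(sequence)
  if (any(grepl("[^ACGT]", sequence)))
    .stopf("melting_temperature: sequences must contain only A/C/G/T")
  if (any(nchar(sequence) < 8L))
    .stopf("melting_temperature: sequences must be at least 8 nt")
  # dinucleotide lookup tables indexed by 4*first + second (A,C,G,T -> 0..3)
  bases <- c("A", "C", "G", "T")
  keys <- as.vector(outer(bases, bases, paste0))        # column-major: AA,CA,GA,TA,...
  dh16 <- .nn_tables$dh[keys]
  ds16 <- .nn_tables$ds[keys]
  base_code <- function(ch) match(ch, bases) - 1L       # ch: single-char vector
  out <- numeric(length(sequence))
  lens <- nchar(sequence)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    s <- sequence[idx]
    cols <- lapply(seq_len(L), function(j) base_code(substr(s, j, j)))
    dh <- numeric(length(idx))
    ds <- numeric(length(idx))
    for (j in seq_len(L - 1L)) {
      k <- cols[[j]] + 4L * cols[[j + 1L]] + 1L         # matches keys order
      dh <- dh + dh16[k]
      ds <- ds + ds16[k]
    }
    for (term in list(cols[[1L]], cols[[L]])) {
      gc <- term == 1L | term == 2L                     # C or G
      dh <- dh + ifelse(gc, 0.1, 2.3)
      ds <- ds + ifelse(gc, -2.8, 4.1)
    }
    ds <- ds + 0.368 * (L - 1L) * log(na_molar)
    ct_div <- ifelse(s == revcomp(s), 1, 4)             # self-complementary
    out[idx] <- 1000 * dh / (ds + .R_GAS * log(oligo_molar / ct_div)) - 273.15
  }
  out
}
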