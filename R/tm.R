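# Nearest-neighbor melting temperature (unified duplex parameters) and GC
# content. Fixed conditions: 50 mM monovalent cation, 50 nM total
# single-strand concentration, no divalent correction. Deterministic.

# Unified NN stacks: dH kcal/mol, dS cal/(mol K).
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# Duplex initiation with a terminal G.C vs terminal A.T pair.
.init_dh <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.init_ds <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Nearest-neighbor oligonucleotide melting temperature
#'
#' Two-state duplex melting temperature from the unified nearest-neighbor
#' thermodynamic parameters, at 50 mM monovalent salt and 50 nM total
#' strand concentration (non-self-complementary convention, CT/4). Salt
#' enters through the entropic correction
#' `dS' = dS + 0.368 (L-1) ln[Na+]`.
#'
#' @param seq Character vector of primer sequences over `A,C,G,T`,
#'   length >= 8 each. Ambiguity codes are rejected: a primer whose
#'   sequence depends on methylation state has no single Tm.
#' @param na_mM Monovalent cation concentration, mM.
#' @param ct_nM Total single-strand concentration, nM.
#' @return Numeric vector of melting temperatures, degrees C.
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")
#' @export
melting_temperature <- function(seq, na_mM = 50, ct_nM = 50) {
  seq <- check_dna(seq, allow = "ACGT", arg = "seq")
  len <- nchar(seq)
  if (any(len < 8L)) abort("primer sequences must be at least 8 bases")
  R <- 1.987
  lnk <- log(ct_nM * 1e-9 / 4)
  vapply(seq_along(seq), function(i) {
    s <- seq[i]; L <- len[i]
    stacks <- substring(s, 1:(L - 1L), 2:L)
    ends <- c(substr(s, 1L, 1L), substr(s, L, L))
    dH <- sum(.nn_dh[stacks]) + sum(.init_dh[ends])
    dS <- sum(.nn_ds[stacks]) + sum(.init_ds[ends]) +
      0.368 * (L - 1L) * log(na_mM / 1000)
    1000 * dH / (dS + R * lnk) - 273.15
  }, numeric(1))
}

#' GC content in percent
#'
#' @param seq Character vector of DNA strings.
#' @return Numeric vector, percent G+C.
#' @export
gc_percent <- function(seq) {
  seq <- check_dna(seq)
  100 * (nchar(gsub("[^GC]", "", seq))) / nchar(seq)
}
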