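# Physical constants and residue-mass tables.
#
# All peptide/protein mass arithmetic in the package flows through the tables
# defined here; nothing else hard-codes a residue mass.

#' @name constants
#' @title Mass and charge constants
#' @description
#' `PROTON_MASS` (1.00728 Da) is the mass of a proton used for charging ions;
#' `WATER_MONO` (18.010565 Da) and `WATER_AVG` (18.0153 Da) are the
#' monoisotopic and average masses of one water molecule added on peptide-bond
#' hydrolysis; `CARBAMIDOMETHYL_MASS` (+57.02146 Da) is the fixed-modification
#' mass shift of cysteine alkylated with iodoacetamide.
#' @keywords internal
NULL

PROTON_MASS <- 1.00728
WATER_MONO <- 18.010565
WATER_AVG <- 18.0153
CARBAMIDOMETHYL_MASS <- 57.02146

# Canonical one-letter amino-acid alphabet. B/J/O/U/Z/X are deliberately
# rejected throughout: ambiguity codes have no defined mass or pKa.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Monoisotopic residue masses (Da, 5 decimals), computed from CODATA/IUPAC
# monoisotopic atomic masses for the residue elemental compositions
# (the values used by Unimod and every MS search engine).
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Average residue masses (Da), composed from IUPAC standard (average) atomic
# weights per residue formula. Single source of truth for protein-level
# average molecular weights; agrees with the ExPASy Compute pI/MW table to
# the last printed digit.
AA_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

# pKa sets for the isoelectric-point charge model.
#
# "bjellqvist": the set behind the ExPASy Compute pI/MW tool. N- and
# C-terminal pKa values are residue-specific where Bjellqvist measured a
# deviation from the default (7.50 / 3.55).
# "emboss": the simpler set used by EMBOSS iep, kept as an alternative.
PKA_SETS <- list(
  bjellqvist = list(
    nterm_default = 7.50,
    nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
              E = 7.70),
    cterm_default = 3.55,
    cterm = c(D = 4.55, E = 4.75),
    positive = c(K = 10.00, R = 12.00, H = 5.98),
    negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
  ),
  emboss = list(
    nterm_default = 8.6,
    nterm = c(),
    cterm_default = 3.6,
    cterm = c(),
    positive = c(K = 10.8, R = 12.5, H = 6.5),
    negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  )
)

# Split a sequence string into residues, validating the alphabet.
# `what` names the offending record in error messages.
split_residues <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (!nzchar(sequence)) {
    stop(what, " is empty", call. = FALSE)
  }
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(residues), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(what, " contains non-canonical residue letter(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  residues
}
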