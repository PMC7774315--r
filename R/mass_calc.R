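# Monoisotopic mass, precursor m/z and y/b fragment m/z computation.

# Validate a fixed-modification table against a sequence. A modification is
# (position, delta_mass, name); carbamidomethyl is only chemically possible
# on cysteine, so that name is checked against the residue.
validate_mods <- function(residues, fixed_mods) {
  if (is.null(fixed_mods)) {
    return(data.frame(position = integer(), delta_mass = numeric(),
                      name = character(), stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(fixed_mods),
            all(c("position", "delta_mass", "name") %in% names(fixed_mods)))
  if (nrow(fixed_mods) == 0L) return(fixed_mods)
  bad <- fixed_mods$position < 1L | fixed_mods$position > length(residues)
  if (any(bad)) {
    stop("modification position(s) out of range: ",
         paste(fixed_mods$position[bad], collapse = ", "),
         " (sequence length ", length(residues), ")", call. = FALSE)
  }
  cam <- fixed_mods$name == "carbamidomethyl"
  if (any(cam & residues[fixed_mods$position] != "C")) {
    stop("carbamidomethyl modification placed on a non-cysteine residue",
         call. = FALSE)
  }
  fixed_mods
}

#' Carbamidomethylation of all cysteines
#'
#' Builds the fixed-modification table placing +57.02146 Da (iodoacetamide
#' alkylation) on every cysteine of the sequence. This is the only built-in
#' fixed modification; arbitrary modifications can be supplied as rows of
#' `(position, delta_mass, name)`.
#'
#' @param sequence Peptide sequence.
#' @return A modification `data.frame` (possibly 0-row).
#' @export
carbamidomethyl_mods <- function(sequence) {
  residues <- split_residues(sequence)
  pos <- which(residues == "C")
  data.frame(position = pos,
             delta_mass = rep(CARBAMIDOMETHYL_MASS, length(pos)),
             name = rep("carbamidomethyl", length(pos)),
             stringsAsFactors = FALSE)
}

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of monoisotopic residue masses plus one water (18.010565 Da) plus any
#' fixed-modification mass shifts.
#'
#' @param sequence Peptide sequence (canonical residues).
#' @param fixed_mods Optional modification `data.frame` with columns
#'   `position`, `delta_mass`, `name`; see [carbamidomethyl_mods()].
#' @return Mass in Da.
#' @examples
#' mono_mass("TYMVR")  # 668.3316
#' @export
mono_mass <- function(sequence, fixed_mods = NULL) {
  residues <- split_residues(sequence)
  fixed_mods <- validate_mods(residues, fixed_mods)
  sum(AA_MONO[residues]) + WATER_MONO + sum(fixed_mods$delta_mass)
}

#' Construct a peptide ion
#'
#' A peptide ion bundles a sequence, its fixed modifications and a charge
#' state with the derived monoisotopic neutral mass `M` and precursor `mz`.
#'
#' @param sequence Peptide sequence.
#' @param charge Positive integer charge state.
#' @param fixed_mods Optional modification table; `carbamidomethyl = TRUE`
#'   is a shortcut adding +57.02146 Da on every cysteine.
#' @param carbamidomethyl If `TRUE`, apply [carbamidomethyl_mods()].
#' @return An object of class `peptide_ion`.
#' @examples
#' peptide_ion("TYMVR", charge = 2)
#' @export
peptide_ion <- function(sequence, charge = 2L, fixed_mods = NULL,
                        carbamidomethyl = FALSE) {
  if (length(charge) != 1L || is.na(charge) || charge < 1L) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  if (carbamidomethyl) {
    fixed_mods <- rbind(fixed_mods, carbamidomethyl_mods(sequence))
  }
  residues <- split_residues(sequence)
  fixed_mods <- validate_mods(residues, fixed_mods)
  M <- mono_mass(sequence, fixed_mods)
  structure(
    list(sequence = sequence, charge = as.integer(charge),
         fixed_mods = fixed_mods, M = M,
         mz = (M + charge * PROTON_MASS) / charge),
    class = "peptide_ion"
  )
}

#' @export
print.peptide_ion <- function(x, ...) {
  mods <- if (nrow(x$fixed_mods)) {
    paste0(" [", paste0(x$fixed_mods$name, "@", x$fixed_mods$position,
                        collapse = ", "), "]")
  } else ""
  cat(sprintf("<peptide ion> %s%s  z=%d  M=%.4f Da  m/z=%.4f\n",
              x$sequence, mods, x$charge, x$M, x$mz))
  invisible(x)
}

#' Precursor m/z of a peptide ion
#'
#' `(M + z * 1.00728) / z` for the monoisotopic neutral mass `M`. Values are
#' kept at full precision; report at 4 decimals (or at the precision of the
#' value being compared against).
#'
#' @param x A `peptide_ion`, or a sequence string.
#' @param charge Charge state, used when `x` is a string.
#' @param fixed_mods Optional modification table, used when `x` is a string.
#' @return m/z value.
#' @examples
#' round(precursor_mz("TYMVR", 2), 4)  # 335.1731
#' @export
precursor_mz <- function(x, charge = 2L, fixed_mods = NULL) {
  if (!inherits(x, "peptide_ion")) {
    x <- peptide_ion(x, charge = charge, fixed_mods = fixed_mods)
  }
  x$mz
}

#' y/b fragment ion m/z
#'
#' For a peptide of length n, `y_i` covers the C-terminal i residues
#' (residue masses + water + charge protons) and `b_i` the N-terminal i
#' residues (residue masses + charge protons), divided by the product charge.
#' Fixed modifications on residues inside the fragment are included.
#'
#' @param x A `peptide_ion` or a sequence string.
#' @param ion_type `"y"` or `"b"`.
#' @param index Fragment index, `1 <= index <= length - 1`.
#' @param product_charge Positive integer (default 1, the usual MRM setting).
#' @param fixed_mods Optional modification table when `x` is a string.
#' @return m/z of the fragment ion.
#' @examples
#' round(fragment_mz("TYMVR", "b", 2), 4)  # 265.1183
#' @export
fragment_mz <- function(x, ion_type = c("y", "b"), index,
                        product_charge = 1L, fixed_mods = NULL) {
  ion_type <- match.arg(ion_type)
  if (!inherits(x, "peptide_ion")) {
    x <- peptide_ion(x, charge = 1L, fixed_mods = fixed_mods)
  }
  residues <- split_residues(x$sequence)
  n <- length(residues)
  if (length(index) != 1L || is.na(index) || index < 1L || index > n - 1L) {
    stop("fragment index must lie in [1, ", n - 1L, "] for a ", n,
         "-residue peptide", call. = FALSE)
  }
  if (product_charge < 1L) {
    stop("product_charge must be a positive integer", call. = FALSE)
  }
  idx <- if (ion_type == "y") seq.int(n - index + 1L, n) else seq.int(1L, index)
  mod_mass <- sum(x$fixed_mods$delta_mass[x$fixed_mods$position %in% idx])
  neutral <- sum(AA_MONO[residues[idx]]) + mod_mass +
    if (ion_type == "y") WATER_MONO else 0
  (neutral + product_charge * PROTON_MASS) / product_charge
}
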