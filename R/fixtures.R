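# Synthetic demonstration sequences.
#
# The deposited UniProt chains of the sorghum ATI markers are not bundled
# with the package; the records below are SYNTHETIC stand-ins authored for
# tests and examples. They are built so that the documented workflow is
# exercised realistically: each chain embeds the published marker peptides
# (quantifier and qualifiers) between tryptic boundaries, one qualifier
# carries an internal R-P site that the proline rule must suppress, and the
# chain sizes (118/116 residues) are typical of the cereal ATI family.
# Their length/mass/pI/identity values are properties of these synthetic
# chains only, not of any database entry.

#' Synthetic two-protein ATI fixture
#'
#' Two synthetic 118- and 116-residue ATI-like chains (`SYN_ATI_A`,
#' `SYN_ATI_B`). Tryptic digestion of `SYN_ATI_A` yields the quantifier
#' ELAAVPSR and qualifiers IYAVSR and TCGLGGPYGPVDPSPVLK; `SYN_ATI_B` yields
#' TYMVR, LVPYCR and the C-terminal peptide TLHGRPFCYALGAEGTTT (whose
#' internal R-P junction is not cleaved by trypsin). These are authored
#' stand-in sequences, not database entries.
#'
#' @return A protein set with two records.
#' @export
synthetic_ati_proteins <- function() {
  protein_set(
    accession = c("SYN_ATI_A", "SYN_ATI_B"),
    description = c(
      "synthetic alpha-amylase/trypsin inhibitor-like chain A (stand-in)",
      "synthetic alpha-amylase/trypsin inhibitor-like chain B (stand-in)"),
    sequence = c(
      paste0("SAGTK", "ELAAVPSR", "IYAVSR", "TCGLGGPYGPVDPSPVLK",
             "ACGVSIGPVVPLPVLK", "QQCCR", "GDLAAIPAGCR", "LDSMPGHCGVSTSK",
             "VVDDAWK", "GPLSGGER", "AELTADNHQWCK", "APGAAGGK"),
      paste0("GVFDK", "TYMVR", "LVPYCR", "ANWCEPGLVIPLNPLPSCR",
             "QLAEVPHDCR", "SGNVGESGLIDLPGCPR", "EMQWDFVR", "AGDSSLK",
             "WDETNPGHGCQMK", "GVTSAEFK", "TLHGRPFCYALGAEGTTT")
    )
  )
}

#' Synthetic background proteome fixture
#'
#' A small synthetic background proteome for uniqueness testing. One record
#' (`SYN_BG_3`) deliberately shares the tryptic peptide GPLSGGER with
#' `SYN_ATI_A`, so that peptide is non-proteotypic against this background.
#'
#' @return A protein set with five records.
#' @export
synthetic_background_proteins <- function() {
  protein_set(
    accession = paste0("SYN_BG_", 1:5),
    description = rep("synthetic background protein (stand-in)", 5),
    sequence = c(
      "MGSSHHLVPRGSAGTENLYFQGAMDPEFKGLVNAK",
      "TTAEDLGAKWDSETNPAHAEQFKGVLDNPR",
      "AVDLSPKGPLSGGERTLNNPQAFAWK",
      "MKVAVLGAAGGIGQALALLLKTQLPSGSER",
      "PNNLQLDETGAHWAVSRDDLMTYMAK"
    )
  )
}
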