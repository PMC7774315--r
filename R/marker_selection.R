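# Quantifier/qualifier peptide selection and MRM transition lists.

#' Proteotypic uniqueness of a peptide within a background proteome
#'
#' A peptide is unique when it occurs as a substring of no background protein
#' other than its parent. Multiple occurrences inside the parent still count
#' as unique. With `il_equivalent = TRUE`, isoleucine and leucine are treated
#' as the same letter before matching: the two residues are isobaric and a
#' triple-quadrupole cannot tell them apart, so an I/L variant elsewhere in
#' the proteome produces the identical transitions. The default keeps them
#' distinct (exact sequence identity, the convention of Skyline's unique
#' peptide filter).
#'
#' @param peptide Peptide sequence (non-empty).
#' @param background A protein set (see [protein_set()]).
#' @param parent_accession Accession of the peptide's parent protein;
#'   occurrences in that record are ignored.
#' @param il_equivalent Treat I and L as indistinguishable (default `FALSE`).
#' @return `TRUE` if the peptide is proteotypic for its parent.
#' @export
is_unique <- function(peptide, background, parent_accession,
                      il_equivalent = FALSE) {
  if (!is.character(peptide) || length(peptide) != 1L || !nzchar(peptide)) {
    stop("peptide must be a non-empty string", call. = FALSE)
  }
  stopifnot(is.data.frame(background), nrow(background) > 0L)
  others <- background[background$accession != parent_accession, , drop = FALSE]
  if (nrow(others) == 0L) return(TRUE)
  pat <- peptide
  seqs <- others$sequence
  if (il_equivalent) {
    pat <- chartr("I", "L", pat)
    seqs <- chartr("I", "L", seqs)
  }
  !any(grepl(pat, seqs, fixed = TRUE))
}

#' Select the quantifier peptide for a protein
#'
#' Applies the three biomarker criteria used to pick one quantifier peptide
#' per protein: (1) the peptide must be unique to its parent within the
#' background proteome; (2) among the survivors the one with the highest
#' summed signal intensity wins; (3) cysteine-containing peptides are
#' excluded outright, because alkylation during sample preparation modifies
#' cysteines and makes their signal depend on derivatisation efficiency.
#' Intensities are caller-supplied (measured or simulated); ties are broken
#' deterministically by lexicographic sequence order.
#'
#' @param candidates Character vector of candidate peptide sequences, or a
#'   [digest()] table (its `peptide` column is used).
#' @param intensities Named numeric vector mapping peptide sequence to summed
#'   peak area. Candidates missing from the map count as intensity 0.
#' @param background A protein set used for the uniqueness filter.
#' @param parent_accession Accession of the protein being assayed.
#' @param il_equivalent Passed to [is_unique()].
#' @return The selected quantifier peptide sequence (length-1 character).
#' @export
select_quantifier <- function(candidates, intensities, background,
                              parent_accession, il_equivalent = FALSE) {
  if (is.data.frame(candidates)) candidates <- candidates$peptide
  candidates <- unique(candidates)
  if (length(candidates) == 0L) {
    stop("no candidate peptides supplied", call. = FALSE)
  }
  keep <- !grepl("C", candidates, fixed = TRUE) &
    vapply(candidates, is_unique, logical(1), background = background,
           parent_accession = parent_accession, il_equivalent = il_equivalent)
  survivors <- candidates[keep]
  if (length(survivors) == 0L) {
    stop("no valid quantifier: every candidate for ", sQuote(parent_accession),
         " is either cysteine-containing or non-unique", call. = FALSE)
  }
  val <- intensities[survivors]
  val[is.na(val)] <- 0
  # highest intensity; lexicographic tie-break
  survivors <- survivors[order(-val, survivors)]
  survivors[[1L]]
}

# Default fragment choice when no measured fragment intensities are given:
# high-index y ions (which retain most of the sequence and usually dominate
# tryptic CID spectra), y_(n-1) downwards, padded with b2 for short peptides.
default_fragments <- function(peptide, n_fragments = 4L) {
  n <- nchar(peptide)
  ys <- seq.int(n - 1L, 2L)
  labels <- paste0("y", ys)
  if (length(labels) < n_fragments) labels <- c(labels, "b2")
  labels[seq_len(min(n_fragments, length(labels)))]
}

parse_fragment_label <- function(label) {
  if (!grepl("^[yb][0-9]+$", label)) {
    stop("malformed fragment label ", sQuote(label),
         " (expected e.g. 'y4' or 'b2')", call. = FALSE)
  }
  list(type = substr(label, 1L, 1L),
       index = as.integer(sub("^[yb]", "", label)))
}

# Skyline-style modified-sequence notation: C[+57.02146] etc.
modified_sequence <- function(sequence, fixed_mods) {
  if (is.null(fixed_mods) || nrow(fixed_mods) == 0L) return(sequence)
  residues <- split_residues(sequence)
  for (i in seq_len(nrow(fixed_mods))) {
    p <- fixed_mods$position[i]
    residues[p] <- sprintf("%s[+%.5f]", residues[p], fixed_mods$delta_mass[i])
  }
  paste(residues, collapse = "")
}

#' Build an MRM transition list
#'
#' Emits one transition row per requested fragment for the quantifier peptide
#' and up to two qualifier peptides of one protein. Between 3 and 4 fragments
#' per peptide are required, the usual MRM design point. Cysteines in
#' qualifier peptides carry the carbamidomethyl fixed modification (the
#' quantifier is cysteine-free by construction, see [select_quantifier()]).
#' Retention time and collision energy are instrument metadata: they are
#' copied from `rt_ce` when provided and left `NA` otherwise, never computed.
#'
#' @param accession Parent protein accession.
#' @param quantifier Quantifier peptide sequence.
#' @param qualifiers Character vector of 0-2 qualifier peptide sequences.
#' @param fragments Named list mapping peptide sequence to a character vector
#'   of 3-4 fragment labels (e.g. `c("y6","y5","y4","y3")`). Peptides missing
#'   from the list get [default_fragments()].
#' @param precursor_charge Precursor charge state (default 2; charges 2 and 3
#'   are the usual tryptic choices).
#' @param rt_ce Optional named list mapping peptide sequence to
#'   `c(RT_min = ..., CE_eV = ...)`.
#' @param role_quantifier,role_qualifier Role labels written to the list.
#' @return A `data.frame` of class `transition_list` with columns `protein`,
#'   `peptide_modified_sequence`, `precursor_mz`, `precursor_charge`,
#'   `fragment_ion`, `product_mz`, `product_charge`, `role`, `RT_min`,
#'   `CE_eV`.
#' @export
build_transition_list <- function(accession, quantifier,
                                  qualifiers = character(),
                                  fragments = list(),
                                  precursor_charge = 2L,
                                  rt_ce = NULL,
                                  role_quantifier = "quantifier",
                                  role_qualifier = "qualifier") {
  if (length(qualifiers) > 2L) {
    stop("at most two qualifier peptides per protein", call. = FALSE)
  }
  peptides <- c(quantifier, qualifiers)
  roles <- c(role_quantifier, rep(role_qualifier, length(qualifiers)))
  rows <- list()
  for (i in seq_along(peptides)) {
    pep <- peptides[i]
    frags <- fragments[[pep]]
    if (is.null(frags)) frags <- default_fragments(pep)
    if (length(frags) < 3L || length(frags) > 4L) {
      stop("peptide ", sQuote(pep), ": 3-4 transitions per peptide are ",
           "required, got ", length(frags), call. = FALSE)
    }
    ion <- peptide_ion(pep, charge = precursor_charge, carbamidomethyl = TRUE)
    meta <- rt_ce[[pep]]
    rt <- if (!is.null(meta)) unname(meta[["RT_min"]]) else NA_real_
    ce <- if (!is.null(meta)) unname(meta[["CE_eV"]]) else NA_real_
    if (!is.na(rt) && rt < 0) stop("RT_min must be >= 0", call. = FALSE)
    if (!is.na(ce) && ce < 0) stop("CE_eV must be >= 0", call. = FALSE)
    for (lab in frags) {
      f <- parse_fragment_label(lab)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = accession,
        peptide_modified_sequence = modified_sequence(pep, ion$fixed_mods),
        precursor_mz = ion$mz,
        precursor_charge = as.integer(precursor_charge),
        fragment_ion = lab,
        product_mz = fragment_mz(ion, f$type, f$index, product_charge = 1L),
        product_charge = 1L,
        role = roles[i],
        RT_min = rt,
        CE_eV = ce,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("transition_list", "data.frame")
  out
}

#' Combine per-protein transition lists
#'
#' @param ... `transition_list` objects.
#' @return A single `transition_list` with rows grouped by protein.
#' @export
c_transition_lists <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("transition_list", "data.frame")
  out
}

#' @export
print.transition_list <- function(x, ...) {
  cat(sprintf("<MRM transition list> %d transitions, %d peptide(s), %d protein(s)\n",
              nrow(x), length(unique(x$peptide_modified_sequence)),
              length(unique(x$protein))))
  print.data.frame(x, digits = 8, row.names = FALSE)
  invisible(x)
}

#' Write / read a transition list as CSV
#'
#' The CSV schema (`protein`, `peptide_modified_sequence`, `precursor_mz`,
#' `precursor_charge`, `fragment_ion`, `product_mz`, `product_charge`,
#' `role`, `RT_min`, `CE_eV`) is importable by Skyline-style tools. Numeric
#' columns are written with full precision so a write/read round trip
#' reproduces the list exactly.
#'
#' @param x A `transition_list`.
#' @param path CSV file path.
#' @return `path` invisibly (writer); a `transition_list` (reader).
#' @export
write_transition_list <- function(x, path) {
  df <- as.data.frame(x)
  for (col in c("precursor_mz", "product_mz", "RT_min", "CE_eV")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_transition_list
#' @export
read_transition_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("protein", "peptide_modified_sequence", "precursor_mz",
                "precursor_charge", "fragment_ion", "product_mz",
                "product_charge", "role", "RT_min", "CE_eV")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("transition-list CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("precursor_mz", "product_mz", "RT_min", "CE_eV")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  class(df) <- c("transition_list", "data.frame")
  df
}

#' Design a full MRM method from protein sequences
#'
#' Orchestrates digestion, quantifier selection and transition-list assembly
#' for every target protein: candidates are generated with [digest()], the
#' quantifier is picked by [select_quantifier()], and up to two qualifier
#' peptides are added (the highest-intensity unique candidates not chosen as
#' quantifier; cysteine-containing peptides are allowed as qualifiers and
#' carry carbamidomethyl).
#'
#' @param targets Protein set of assay targets.
#' @param background Protein set of the background proteome (for uniqueness).
#'   Targets are appended automatically if absent.
#' @param intensities Named numeric vector of summed peak areas per peptide
#'   (measured or simulated; candidates missing from it count as 0).
#' @param enzyme,missed_cleavages,length_range Passed to [digest()].
#' @param n_qualifiers Number of qualifier peptides per protein (default 2).
#' @param fragments,precursor_charge,rt_ce Passed to
#'   [build_transition_list()].
#' @param il_equivalent Passed to the uniqueness filter.
#' @return A list with elements `transitions` (a `transition_list`) and
#'   `report` (per-protein candidate counts and filter attrition).
#' @export
design_mrm_method <- function(targets, background, intensities,
                              enzyme = "trypsin", missed_cleavages = 0L,
                              length_range = length_window("preselect"),
                              n_qualifiers = 2L, fragments = list(),
                              precursor_charge = 2L, rt_ce = NULL,
                              il_equivalent = FALSE) {
  extra <- targets[!targets$accession %in% background$accession, , drop = FALSE]
  background <- rbind(background, extra)
  lists <- list()
  report <- list()
  for (i in seq_len(nrow(targets))) {
    acc <- targets$accession[i]
    cand <- digest(targets[i, , drop = FALSE], enzyme = enzyme,
                   missed_cleavages = missed_cleavages,
                   length_range = length_range)
    quant <- select_quantifier(cand, intensities, background, acc,
                               il_equivalent = il_equivalent)
    pool <- setdiff(unique(cand$peptide), quant)
    uniq <- pool[vapply(pool, is_unique, logical(1), background = background,
                        parent_accession = acc,
                        il_equivalent = il_equivalent)]
    val <- intensities[uniq]
    val[is.na(val)] <- 0
    quals <- uniq[order(-val, uniq)][seq_len(min(n_qualifiers, length(uniq)))]
    lists[[i]] <- build_transition_list(acc, quant, quals,
                                        fragments = fragments,
                                        precursor_charge = precursor_charge,
                                        rt_ce = rt_ce)
    report[[i]] <- data.frame(
      accession = acc,
      n_candidates = length(unique(cand$peptide)),
      n_cys_free = sum(!grepl("C", unique(cand$peptide), fixed = TRUE)),
      n_unique = length(uniq) + 1L,
      quantifier = quant,
      qualifiers = paste(quals, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  list(transitions = do.call(c_transition_lists, lists),
       report = do.call(rbind, report))
}
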