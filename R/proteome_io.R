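# Protein record I/O and protein-level descriptors.

#' Construct a set of protein records
#'
#' A protein set is a plain `data.frame` with columns `accession`,
#' `description` and `sequence` (uppercase, 20-letter canonical alphabet).
#' Ambiguity letters (B/J/O/U/Z/X) are rejected because downstream mass and
#' pI computations are undefined for them.
#'
#' @param accession Character vector of non-empty, unique accessions.
#' @param sequence Character vector of amino-acid sequences (same length).
#' @param description Optional character vector of free-text descriptions.
#' @return A `data.frame` with columns `accession`, `description`, `sequence`.
#' @examples
#' protein_set("X1", "GWGG")
#' @export
protein_set <- function(accession, sequence, description = "") {
  accession <- as.character(accession)
  sequence <- toupper(gsub("[[:space:]]", "", as.character(sequence)))
  description <- rep_len(as.character(description), length(accession))
  if (length(sequence) != length(accession)) {
    stop("accession and sequence must have the same length", call. = FALSE)
  }
  if (any(!nzchar(accession)) || anyNA(accession)) {
    stop("every accession must be a non-empty string", call. = FALSE)
  }
  if (anyDuplicated(accession)) {
    stop("duplicated accession(s): ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(sequence)) {
    split_residues(sequence[i], what = paste0("record ", sQuote(accession[i])))
  }
  data.frame(accession = accession, description = description,
             sequence = sequence, stringsAsFactors = FALSE)
}

# Pull a UniProt-style accession out of a FASTA header first token:
# "sp|P81367|IAA4_SORBI" -> "P81367"; otherwise the token itself.
parse_fasta_header <- function(header) {
  first <- sub("\\s.*$", "", header)
  description <- sub("^\\S*\\s*", "", header)
  parts <- strsplit(first, "|", fixed = TRUE)[[1L]]
  accession <- if (length(parts) >= 2L && nzchar(parts[2L])) parts[2L] else first
  list(accession = accession, description = description)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences may be wrapped over any number of lines; whitespace is stripped
#' and letters uppercased. For UniProt-style headers (`>db|ACC|ID desc`) the
#' accession is the middle field; otherwise the first whitespace-delimited
#' token. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A protein set (see [protein_set()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) {
                   stop("failed to parse FASTA file ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  if (length(aa) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  headers <- lapply(names(aa), parse_fasta_header)
  accession <- vapply(headers, `[[`, character(1), "accession")
  description <- vapply(headers, `[[`, character(1), "description")
  sequence <- as.character(aa)
  empty <- !nzchar(gsub("[[:space:]]", "", sequence))
  if (any(empty)) {
    stop("record ", sQuote(accession[which(empty)[1L]]),
         " has an empty sequence", call. = FALSE)
  }
  protein_set(accession, sequence, description)
}

#' Write a protein set to FASTA
#'
#' Sequences are wrapped at 60 characters per line. Reading the file back
#' with [read_fasta()] recovers the identical records.
#'
#' @param proteins A protein set.
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(is.data.frame(proteins),
            all(c("accession", "description", "sequence") %in% names(proteins)))
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- ifelse(nzchar(proteins$description),
                      paste(proteins$accession, proteins$description),
                      proteins$accession)
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}

#' Average molecular weight of a protein or peptide chain
#'
#' Sum of average residue masses plus one water (18.0153 Da), using the
#' IUPAC average-atomic-weight residue table embedded in the package. This is
#' the convention of the ExPASy Compute pI/MW tool, so values agree with
#' UniProt's printed MW for the same chain. Values are returned at full
#' precision; round to 2 decimals for reporting.
#'
#' @param sequence Character vector of sequences (or a protein set, in which
#'   case its `sequence` column is used).
#' @return Numeric vector of masses in Da.
#' @examples
#' round(average_mw("G"), 2)  # 75.07
#' @export
average_mw <- function(sequence) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence
  vapply(sequence, function(s) {
    sum(AA_AVG[split_residues(s)]) + WATER_AVG
  }, numeric(1), USE.NAMES = FALSE)
}

# Net charge of a chain at a given pH under the Henderson-Hasselbalch
# two-state model with the chosen pKa set.
net_charge_at_ph <- function(residues, ph, pka) {
  nterm_pka <- pka$nterm_default
  if (residues[1L] %in% names(pka$nterm)) nterm_pka <- pka$nterm[[residues[1L]]]
  cterm_pka <- pka$cterm_default
  last <- residues[length(residues)]
  if (last %in% names(pka$cterm)) cterm_pka <- pka$cterm[[last]]
  counts <- table(factor(residues, levels = AA_ALPHABET))
  pos <- 1 / (1 + 10^(ph - nterm_pka))
  for (aa in names(pka$positive)) {
    pos <- pos + counts[[aa]] / (1 + 10^(ph - pka$positive[[aa]]))
  }
  neg <- 1 / (1 + 10^(cterm_pka - ph))
  for (aa in names(pka$negative)) {
    neg <- neg + counts[[aa]] / (1 + 10^(pka$negative[[aa]] - ph))
  }
  pos - neg
}

#' Isoelectric point of a protein or peptide
#'
#' pH at which the net charge of the Bjellqvist charge model is zero, found
#' by bisection on \[0, 14\]. The default pKa set is the one behind the
#' ExPASy Compute pI/MW tool; `"emboss"` selects the EMBOSS iep set.
#'
#' @param sequence Character vector of sequences (or a protein set).
#' @param pka_set `"bjellqvist"` (default) or `"emboss"`.
#' @param tol Bisection tolerance on pH (default 1e-4).
#' @return Numeric vector of pI values.
#' @examples
#' round(isoelectric_point("GGGGG"), 2)
#' @export
isoelectric_point <- function(sequence, pka_set = c("bjellqvist", "emboss"),
                              tol = 1e-4) {
  pka_set <- match.arg(pka_set)
  pka <- PKA_SETS[[pka_set]]
  if (is.data.frame(sequence)) sequence <- sequence$sequence
  vapply(sequence, function(s) {
    residues <- split_residues(s)
    lo <- 0; hi <- 14
    # net charge is monotonically decreasing in pH
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (net_charge_at_ph(residues, mid, pka) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
}

#' Protein-level descriptor table
#'
#' Length, average molecular weight (2 decimals) and isoelectric point
#' (2 decimals) for every record, in the layout of a UniProt protein summary.
#'
#' @param proteins A protein set.
#' @param pka_set Passed to [isoelectric_point()].
#' @return A `data.frame` with columns `accession`, `length`, `mw`, `pi`.
#' @export
protein_descriptors <- function(proteins, pka_set = "bjellqvist") {
  data.frame(
    accession = proteins$accession,
    length = nchar(proteins$sequence),
    mw = round(average_mw(proteins), 2),
    pi = round(isoelectric_point(proteins, pka_set = pka_set), 2),
    stringsAsFactors = FALSE
  )
}
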