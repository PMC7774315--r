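# In-silico proteolytic digestion.

#' Peptide-length window presets
#'
#' Two windows commonly used when generating candidate peptides for a
#' targeted assay: `"preselect"` keeps peptides of 4-25 residues (the window
#' used to preselect ATI candidates), `"skyline"` keeps 5-30 residues (the
#' Skyline peptide-settings default window). The active window is always an
#' explicit argument of [digest()]; these presets just name the two choices.
#'
#' @param name `"preselect"` or `"skyline"`.
#' @return Integer vector `c(min_len, max_len)`.
#' @export
length_window <- function(name = c("preselect", "skyline")) {
  switch(match.arg(name),
         preselect = c(4L, 25L),
         skyline = c(5L, 30L))
}

# 0-based cut positions (cleave after position i). `n` cut positions plus the
# sequence ends define the fully cleaved fragments.
cleavage_positions <- function(residues, enzyme) {
  n <- length(residues)
  is_kr <- residues %in% c("K", "R")
  keep <- switch(enzyme,
    "trypsin" = is_kr & c(residues[-1L] != "P", TRUE),
    "trypsin/P" = is_kr,
    stop("unknown enzyme rule: ", sQuote(enzyme),
         " (available: 'trypsin', 'trypsin/P')", call. = FALSE)
  )
  sites <- which(keep)
  sites[sites < n]  # a terminal K/R is an end, not an internal cut
}

#' In-silico digestion of protein sequences
#'
#' Cleaves each protein with the named enzyme rule, keeping peptides with up
#' to `missed_cleavages` retained internal sites whose length falls inside
#' `length_range`. `"trypsin"` cuts C-terminal of K or R except before
#' proline; `"trypsin/P"` disables the proline suppression. The C-terminal
#' peptide is always a candidate regardless of its final residue. Output is
#' ordered by parent, then start position, then length.
#'
#' @param proteins A protein set (see [protein_set()]) or a single sequence
#'   string.
#' @param enzyme `"trypsin"` (default) or `"trypsin/P"`.
#' @param missed_cleavages Maximum number of retained internal cleavage sites
#'   (default 0).
#' @param length_range Integer `c(min_len, max_len)`; see [length_window()].
#'   Default `c(1L, Inf)` (no filter).
#' @return A `data.frame` with columns `accession`, `peptide`, `start`, `end`,
#'   `missed_cleavages` (1-based inclusive positions in the parent).
#' @examples
#' digest("GAVKRLDER")$peptide              # "GAVK" "R" "LDER"
#' digest("GAKPLR")$peptide                 # "GAKPLR": no cut before proline
#' digest("GAVKRLDER", missed_cleavages = 1)$peptide
#' @export
digest <- function(proteins, enzyme = "trypsin", missed_cleavages = 0L,
                   length_range = c(1L, Inf)) {
  if (is.character(proteins)) {
    proteins <- protein_set(paste0("seq", seq_along(proteins)), proteins)
  }
  if (length(length_range) != 2L || length_range[1L] > length_range[2L] ||
      length_range[1L] < 1L) {
    stop("length_range must be c(min_len, max_len) with 1 <= min <= max",
         call. = FALSE)
  }
  if (missed_cleavages < 0L) {
    stop("missed_cleavages must be >= 0", call. = FALSE)
  }
  out <- vector("list", nrow(proteins))
  for (p in seq_len(nrow(proteins))) {
    seq_str <- proteins$sequence[p]
    residues <- split_residues(seq_str,
                               what = paste0("record ",
                                             sQuote(proteins$accession[p])))
    n <- length(residues)
    cuts <- cleavage_positions(residues, enzyme)
    # fragment boundaries: starts follow a cut (or position 1), ends are cuts
    # (or position n)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    k <- length(starts)
    recs <- list()
    for (i in seq_len(k)) {
      for (j in i:min(k, i + missed_cleavages)) {
        len <- ends[j] - starts[i] + 1L
        if (len >= length_range[1L] && len <= length_range[2L]) {
          recs[[length(recs) + 1L]] <- data.frame(
            accession = proteins$accession[p],
            peptide = substr(seq_str, starts[i], ends[j]),
            start = starts[i], end = ends[j],
            missed_cleavages = j - i,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    if (length(recs) > 0L) {
      df <- do.call(rbind, recs)
      df <- df[order(df$start, df$end - df$start), , drop = FALSE]
      out[[p]] <- df
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(accession = character(), peptide = character(),
                      start = integer(), end = integer(),
                      missed_cleavages = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a peptide table as delimited text
#'
#' @param peptides Output of [digest()].
#' @param path Output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_peptides <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
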