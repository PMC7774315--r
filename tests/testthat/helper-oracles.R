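# Independent oracles used across the suite. These deliberately share no
# code with the package internals.

# Brute-force digestion oracle: enumerate every substring and keep those
# whose boundaries are valid cleavage boundaries and whose number of
# retained internal sites and length satisfy the settings.
oracle_digest <- function(sequence, missed_cleavages = 0L,
                          min_len = 1L, max_len = Inf,
                          proline_rule = TRUE) {
  residues <- strsplit(sequence, "")[[1L]]
  n <- length(residues)
  is_site <- function(i) {
    # cleavage after position i (0 = N-terminus, n = C-terminus)
    if (i == 0L || i == n) return(TRUE)
    residues[i] %in% c("K", "R") &&
      (!proline_rule || residues[i + 1L] != "P")
  }
  out <- character(0)
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (!is_site(s - 1L) || !is_site(e)) next
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      internal <- if (e > s) {
        sum(vapply(s:(e - 1L), is_site, logical(1)))
      } else 0L
      if (internal <= missed_cleavages) {
        out <- c(out, substr(sequence, s, e))
      }
    }
  }
  sort(out)
}

# Brute-force global affine-gap alignment score: enumerate all alignments
# recursively (no DP), scoring a gap run of length L as open + extend * L.
# Only usable for very short sequences.
oracle_align_score <- function(a, b, submat, open, extend) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  rec <- function(i, j, prev) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, submat[ca[i], cb[j]] + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= length(ca)) {  # gap in b
      cost <- extend + if (prev == "gb") 0 else open
      best <- max(best, -cost + rec(i + 1L, j, "gb"))
    }
    if (j <= length(cb)) {  # gap in a
      cost <- extend + if (prev == "ga") 0 else open
      best <- max(best, -cost + rec(i, j + 1L, "ga"))
    }
    best
  }
  rec(1L, 1L, "m")
}

random_protein <- function(n, letters = c("A", "C", "D", "E", "F", "G", "H",
                                          "I", "K", "L", "M", "N", "P", "Q",
                                          "R", "S", "T", "V", "W", "Y")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Minimal measurement table builder for quantification tests.
make_table <- function(rows, ...) {
  measurement_table(do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], replicate = as.integer(r[[2]]),
               analyte_id = r[[3]], peak_area = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)
  })), ...)
}

# Fabricate a pairwise_alignment object from two gapped strings.
fake_alignment <- function(aligned_a, aligned_b) {
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b, score = NA,
                 substitution_matrix = "BLOSUM62", gap_open = 10,
                 gap_extend = 0.5),
            class = "pairwise_alignment")
}
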