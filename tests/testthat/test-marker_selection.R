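test_that("proteotypic uniqueness is literal substring matching", {
  bg <- protein_set(
    c("P1", "P2", "P3", "P4", "P5"),
    c("GAVKELAAVPSRLDER",      # parent
      "TTTELAAVPSRGGG",        # shares the peptide verbatim
      "AAAAKLLLLR",
      "MNPQRSTVWY",
      "GAVKGAVK"))
  expect_false(is_unique("ELAAVPSR", bg, "P1"))
  expect_true(is_unique("LDER", bg, "P1"))
  # two occurrences inside the parent only: still unique (brute-force check)
  expect_true(is_unique("GAVK", bg[bg$accession != "P1", ], "P5"))
  hits <- vapply(bg$sequence, function(s) grepl("GAVK", s, fixed = TRUE),
                 logical(1))
  expect_identical(unname(which(hits)), c(1L, 5L))
  expect_error(is_unique("", bg, "P1"), "non-empty")
})

test_that("I/L-equivalent matching treats the isobaric residues as one", {
  bg <- protein_set(c("A", "B"), c("KGIVDLRK", "KGLVDIRK"))
  expect_true(is_unique("GIVDLR", bg, "A"))
  expect_false(is_unique("GIVDLR", bg, "A", il_equivalent = TRUE))
})

test_that("quantifier selection applies the three biomarker criteria", {
  proteins <- synthetic_ati_proteins()
  bg <- rbind(proteins, synthetic_background_proteins())
  # cysteine-containing candidates are excluded despite higher intensity
  sel <- select_quantifier(c("ELAAVPSR", "LVPYCR"),
                           c(ELAAVPSR = 1e6, LVPYCR = 2e6), bg, "SYN_ATI_A")
  expect_identical(sel, "ELAAVPSR")
  # single surviving candidate returns itself
  expect_identical(
    select_quantifier("IYAVSR", c(IYAVSR = 10), bg, "SYN_ATI_A"), "IYAVSR")
  # deterministic lexicographic tie-break at equal intensity
  expect_identical(
    select_quantifier(c("IYAVSR", "ELAAVPSR"),
                      c(IYAVSR = 5, ELAAVPSR = 5), bg, "SYN_ATI_A"),
    "ELAAVPSR")
  # non-unique peptides are filtered out (GPLSGGER is shared with background)
  expect_identical(
    select_quantifier(c("GPLSGGER", "VVDDAWK"),
                      c(GPLSGGER = 9e9, VVDDAWK = 1), bg, "SYN_ATI_A"),
    "VVDDAWK")
  expect_error(
    select_quantifier("LVPYCR", c(LVPYCR = 1), bg, "SYN_ATI_B"),
    "no valid quantifier")
})

test_that("selected quantifiers are always unique and cysteine-free", {
  set.seed(404)
  for (i in 1:25) {
    seqs <- vapply(1:4, function(j) random_protein(sample(30:60, 1)),
                   character(1))
    bg <- protein_set(paste0("R", 1:4), seqs)
    cand <- digest(bg[1, , drop = FALSE], length_range = c(4, 25))$peptide
    ints <- stats::setNames(stats::runif(length(cand), 1, 100), cand)
    sel <- tryCatch(select_quantifier(cand, ints, bg, "R1"),
                    error = function(e) NULL)
    if (!is.null(sel)) {
      expect_false(grepl("C", sel, fixed = TRUE))
      expect_true(is_unique(sel, bg, "R1"))
    }
  }
})

test_that("transition lists carry 3-4 computed transitions per peptide", {
  tl <- build_transition_list(
    "SYN_ATI_A", "ELAAVPSR",
    qualifiers = c("IYAVSR", "TCGLGGPYGPVDPSPVLK"),
    fragments = list(ELAAVPSR = c("y6", "y5", "y4", "y3")),
    rt_ce = list(ELAAVPSR = c(RT_min = 8.59, CE_eV = 14.1)))
  expect_s3_class(tl, "transition_list")
  expect_equal(length(unique(tl$peptide_modified_sequence)), 3L)
  counts <- table(tl$peptide_modified_sequence)
  expect_true(all(counts >= 3 & counts <= 4))
  # quantifier fragments as requested, with computed product m/z
  q <- tl[tl$role == "quantifier", ]
  expect_equal(q$fragment_ion, c("y6", "y5", "y4", "y3"))
  expect_equal(round(q$product_mz, 4),
               c(600.3464, 529.3093, 458.2722, 359.2037))
  expect_equal(unique(q$RT_min), 8.59)
  expect_equal(unique(q$CE_eV), 14.1)
  # cysteines in qualifiers carry carbamidomethyl in sequence and mass
  cysq <- tl[grepl("^TC", tl$peptide_modified_sequence), ]
  expect_match(unique(cysq$peptide_modified_sequence),
               "C[+57.02146]", fixed = TRUE)
  expect_equal(unique(round(cysq$precursor_mz, 4)),
               round((mono_mass("TCGLGGPYGPVDPSPVLK") + 57.02146 +
                        2 * 1.00728) / 2, 4))
})

test_that("transition-list construction rejects invalid requests", {
  expect_error(build_transition_list("A", "ELAAVPSR",
                                     fragments = list(ELAAVPSR = c("y3", "y4"))),
               "3-4 transitions")
  expect_error(build_transition_list("A", "ELAAVPSR",
                                     fragments = list(
                                       ELAAVPSR = c("y8", "y3", "y4"))),
               "index")
  expect_error(build_transition_list("A", "Q", qualifiers = c("B", "C", "D")),
               "at most two")
  # quantifier-only list is valid
  tl <- build_transition_list("A", "ELAAVPSR")
  expect_equal(unique(tl$role), "quantifier")
})

test_that("transition lists round-trip through CSV exactly", {
  method <- design_mrm_method(
    synthetic_ati_proteins(), synthetic_background_proteins(),
    c(ELAAVPSR = 2e6, TYMVR = 1e6, IYAVSR = 5e5, AGDSSLK = 4e5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_list(method$transitions, path)
  back <- read_transition_list(path)
  expect_equal(back, method$transitions)
  expect_identical(back$precursor_mz, method$transitions$precursor_mz)
})

test_that("the synthetic two-ATI fixture yields the published quantifiers", {
  # any intensity map ranking the published markers highest among
  # cysteine-free candidates must select exactly these two peptides
  method <- design_mrm_method(
    synthetic_ati_proteins(), synthetic_background_proteins(),
    c(ELAAVPSR = 2e6, TYMVR = 1.5e6, IYAVSR = 1e6, VVDDAWK = 9e5))
  expect_identical(method$report$quantifier, c("ELAAVPSR", "TYMVR"))
  expect_false(any(grepl("C", method$report$quantifier, fixed = TRUE)))
})
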