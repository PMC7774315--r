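---
title: "Designing and validating a targeted MRM assay for cereal alpha-amylase/trypsin inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating a targeted MRM assay for cereal alpha-amylase/trypsin inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmati)
```

## The problem

Alpha-amylase/trypsin inhibitors (ATIs) are small (10-16 kDa), cysteine-rich
cereal seed proteins implicated in non-celiac wheat sensitivity. Comparing
ATI levels across cultivars calls for a targeted LC-MS/MS assay in multiple
reaction monitoring (MRM) mode: for each marker protein one monitors a few
precursor-to-fragment ion transitions of proteotypic peptides and uses their
integrated peak areas (PA) for relative quantification. `mrmati` implements
the computational side of that workflow end to end: in-silico assay design
from protein sequences, internal-standard (IS) normalisation and relative
quantification of peak-area tables, ICH-style method validation, and a
synthetic data generator with known ground truth so every stage can be
verified without an instrument.

## From sequence to transition list

**Digestion.** `digest()` applies the tryptic rule (cleave C-terminal of K
or R, suppressed when the next residue is proline; `"trypsin/P"` disables
the suppression) with explicit missed-cleavage control. Two candidate
length windows are shipped as presets, because both are in common use for
candidate preselection: `length_window("preselect")` keeps 4-25 residues
and `length_window("skyline")` keeps 5-30. Neither is applied implicitly;
the active window is always an argument. Peptides carry their 1-based
parent coordinates, so a zero-missed-cleavage digest partitions the parent
exactly — a property the test suite checks against a brute-force substring
oracle.

**Masses.** All mass arithmetic flows through a single embedded table of
monoisotopic residue masses (5 decimals, the residue compositions used by
Unimod), with water 18.010565 Da and proton 1.00728 Da. The precursor of a
peptide of neutral mass $M$ at charge $z$ sits at $(M + z \cdot 1.00728)/z$;
fragment ions follow the standard y/b conventions,

$$ y_i = \frac{\sum_{\text{C-term } i} m_r + 18.010565 + z\,1.00728}{z},
\qquad
b_i = \frac{\sum_{\text{N-term } i} m_r + z\,1.00728}{z}, $$

which satisfy the complementarity identity $b_i + y_{n-i} - 2 \cdot 1.00728
= M$, asserted to 1e-4 across the fixture peptides. Carbamidomethylation
(+57.02146 Da on C, from iodoacetamide alkylation) is the only built-in
fixed modification; arbitrary `(position, delta_mass, name)` rows extend
the list. Masses are kept at full precision internally and rounded only for
reporting (4 decimals for m/z by default, or the precision of whatever
printed value is being compared).

**Marker selection.** `select_quantifier()` encodes the three biomarker
criteria used in targeted ATI work: the quantifier peptide must be (1)
proteotypic — a substring of no background protein other than its parent —
(2) the strongest responder among the survivors, and (3) cysteine-free,
because alkylation chemistry makes cysteine-peptide signals depend on
derivatisation efficiency. Intensities are always caller-supplied; the
package never invents them. Ties break lexicographically so selection is
deterministic. Uniqueness is literal substring matching by default; a
config flag treats I and L as equivalent, since the two residues are
isobaric and indistinguishable by a triple quadrupole — the default keeps
the stricter, conventional behaviour. `build_transition_list()` emits 3-4
transitions per peptide (the usual MRM design point), computes product m/z
from the mass module, and stores retention time and collision energy purely
as instrument metadata. The CSV schema round-trips bit-exactly.

## Sequence comparison

`global_align()` wraps a Needleman-Wunsch global alignment under affine gap
penalties (gap of length $L$ costs `gap_open + gap_extend * L`), defaulting
to BLOSUM62 with gap open 10 and extend 0.5 — common defaults of
interactive alignment tools, and exposed as arguments because different
tools ship different settings (`alignment_parameter_grid()` scans a small
grid when reproducing a figure whose provenance is unknown). Percent
identity divides identical columns by the full alignment length *including
gap columns*; gap columns never count as matches. This denominator
convention matters: it is the one under which a pair of ~120-residue ATI
homologs with 41 identical positions comes out near 33.6% rather than the
higher value a gap-excluded denominator would give.

## Quantification model

The internal standard (here the tetrapeptide GWGG, [M+H]+ 376.2) is spiked
at a fixed level *after* sample cleanup, so its measured area reflects
ionization-stage drift only. `is_normalize()` multiplies every analyte area
of a sample x replicate by (IS area in water)/(IS area in that cell),
which exactly cancels any multiplicative factor shared by IS and analytes
— and deliberately nothing else. Digestion-stage matrix suppression, which
the IS never experiences, is *not* corrected; it is monitored instead via a
spiked digestion-control protein (beta-lactoglobulin, quantifier GLDIQK)
and quantified with `matrix_recovery()`. The synthetic-data module makes
this separation explicit (below), and `recovery_experiment()` demonstrates
the residual bias `suppression - 1` analytically.

`relative_ati_content()` quantifies each protein by its quantifier peptide
only (qualifiers serve identification), sums proteins to a total, and
divides by the effective flour mass of one injection:

```
flour_mass_mg x (digest_aliquot_mL / extraction_volume_mL)
             x (injected_volume_uL / 1000 / final_volume_mL)
```

with defaults 100 mg, 0.4/1.0 mL, 10 uL/5 mL (0.08 mg per injection). The
published workflow states the masses and volumes but not the per-injection
bookkeeping, so the chain is explicit and every factor overridable.
Replicates aggregate as mean and (n-1) SD of per-replicate results, not of
pooled areas. Composition percentages sum to 100 whenever the total is
positive and are reported as `NA` (never 0/0) for all-zero samples.

## Method validation

`validation_report()` assembles the ICH criteria per analyte: ordinary
least squares of PA on amount ($y = a + bx$ over all replicate points),
$R^2$, and detection limits

$$ \mathrm{LOD} = 3\,S_a / b, \qquad \mathrm{LOQ} = 10\,S_a / b, $$

in the unit of the calibration amounts (units are carried per analyte and
never converted implicitly, since IS calibrations are typically in pg of
peptide while protein calibrations are in ng). $S_a$ is by default the OLS
standard error of the intercept — the usual ICH reading of "standard
deviation of the intercept" — with the residual SD available as the second
common variant (`sa_method = "residual_sd"`). `rsd_percent()` uses the
sample SD throughout (precision figures come from triplicates); intraday
%RSD is computed from within-day replicates and interday %RSD from
day-level means. A noiseless calibration yields $S_a = 0$, $R^2 = 1$,
LOD = LOQ = 0 exactly, and LOQ/LOD = 10/3 identically — both are asserted
in the tests.

## The synthetic-data generator

`simulate_measurements()` draws, per sample x replicate,

```
analyte PA = truth x digestion_suppression x ionization_factor x noise
bLG PA     = blg_true x digestion_suppression x ionization_factor x noise
IS PA      = is_true  x                        ionization_factor x noise
```

The IS line is the modelling core: exempting the IS from digestion
suppression encodes the workflow fact that it is spiked after cleanup.
Replicate noise is multiplicative lognormal with exact unit mean (peak
areas are positive and precision is quoted as %RSD); calibration series get
additive Gaussian noise on a straight line, with negative areas floored at
zero and flagged. Everything is deterministic under the config seed, and
the generator leaves the caller's RNG stream untouched.

The default scenario (`default_scenario()`) has 15 samples with true totals
log-spaced over ~3.8e3-5.3e5 PA per mg flour (the dynamic range observed
across sorghum cultivars), the dominant protein's share sweeping 59-92%
(the observed composition range), ionization factors sweeping the observed
±4% band deterministically, CV 5% and 3 replicates. Digestion suppression
is 1 in the default scenario so that parameter-recovery runs isolate the
stage IS normalisation can actually correct; suppression is exercised
explicitly in dedicated tests (e.g. a 0.09 factor reproducing a 91% loss
of the digestion monitor while the IS is untouched). Calibration defaults
(six amounts 10-200 pg, slope 57.9, intercept 100, additive SD 150) keep
simulated series in the published linearity regime ($R^2 \ge 0.989$).

What the generator does *not* emulate: chromatographic interference,
retention-time drift, isotope patterns, additive baseline noise on
measurement tables, nonlinear detector saturation, or digestion kinetics.
Passing parameter-recovery tests therefore show that the analysis correctly
inverts the assumed multiplicative error structure — not that real matrix
effects are fully captured.

## Numerical and design choices

* **Average masses and pI.** Protein-level MW uses an embedded IUPAC
  average residue-mass table plus one water (18.0153 Da); pI solves the
  Bjellqvist charge model (the pKa set behind the ExPASy Compute pI/MW
  tool, with residue-specific terminal pKa values) for zero net charge by
  bisection on \[0, 14\] to 1e-4 — the charge is monotone in pH, so
  bisection always converges. The EMBOSS pKa set is available as an option.
  Chains are treated exactly as supplied (no signal-peptide processing, no
  N-terminal methionine clipping).
* **Determinism.** Every ordering ambiguity has a documented tie-break:
  digestion output sorts by start then length, quantifier ties break
  lexicographically, simulation run *k* uses seed + *k*.
* **Degenerate inputs** are first-class: zero-mean %RSD, singular
  calibrations, zero IS areas, all-zero samples and empty candidate pools
  all raise informative errors (or `NA`, where the quantity is undefined)
  rather than propagating NaN.
* **Demonstration sequences.** The package ships *synthetic* ATI-like
  chains (`synthetic_ati_proteins()`, 118/116 residues) that embed the
  published marker peptides — quantifiers ELAAVPSR and TYMVR, qualifiers
  IYAVSR, TCGLGGPYGPVDPSPVLK, LVPYCR and TLHGRPFCYALGAEGTTT — between
  tryptic boundaries, one of them behind an R-P junction that the proline
  rule must protect. They are authored stand-ins for tests and examples,
  clearly labelled as such: database-derived properties (exact digest
  counts, MW, pI, pairwise identity of the deposited chains) are *not*
  claims these fixtures can support, and the corresponding end-to-end check
  in the test suite requires a user-supplied FASTA of the deposited
  entries.
* **Problem sizes in the checks.** The oracle-equivalence suites use 200
  random sequences of length <= 50 (digestion) and a dozen length-<= 7
  pairs (alignment, where the brute-force enumeration is exponential); the
  parameter-recovery experiment uses the 15-sample default scenario with
  200 Monte-Carlo runs; the quantification-invariant property suite uses
  1000 randomised tables. These sizes give stable pass/fail behaviour in
  seconds to a couple of minutes on one CPU.

## A worked design run

```{r design}
targets <- synthetic_ati_proteins()
background <- synthetic_background_proteins()
intensities <- c(ELAAVPSR = 2e6, TYMVR = 1.5e6, IYAVSR = 1e6,
                 AGDSSLK = 9e5, VVDDAWK = 8e5)
method <- design_mrm_method(targets, background, intensities)
method$report
head(method$transitions, 4)
```

```{r quantify}
cfg <- default_scenario(seed = 7)
tab <- simulate_measurements(cfg)
norm <- is_normalize(tab, is_reference_area = cfg$is_true_area)
quant <- relative_ati_content(norm, cfg$proteins)
head(quant$summary[, 1:4])
recovery_experiment(cfg, n_runs = 50)
```

## Known limitations

* Retention times and collision energies are instrument-bound and carried
  as metadata only; the package neither predicts nor optimises them.
* Absolute quantification (isotope-labelled standards) is out of scope;
  results are relative peak areas per mg flour.
* The uniqueness filter is substring-based within the supplied background
  proteome; it does not model near-isobaric interference beyond the
  optional I/L equivalence.
* Statistical inference across conditions (ANOVA and post-hoc letters) is
  deliberately excluded; `group_summary()` provides the mean ± SD substrate
  only.
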