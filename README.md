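# mrmati

Targeted LC–MS/MS (MRM) assay design and relative quantification for cereal
α-amylase/trypsin inhibitors (ATIs).

ATIs are small, cysteine-rich seed proteins (10–16 kDa) implicated in
non-celiac wheat sensitivity. Measuring their relative abundance across
cultivars is done with multiple reaction monitoring: a triple-quadrupole
instrument watches a few precursor→fragment transitions of proteotypic
peptides per marker protein and integrates their peak areas (PA). `mrmati`
implements the computational workflow around such an assay, for analysts
building or auditing one:

* **Assay design** — in-silico tryptic digestion (K/R cleavage with proline
  suppression, missed-cleavage and length control), monoisotopic precursor
  and y/b fragment m/z with fixed modifications (carbamidomethyl-C built
  in), and quantifier/qualifier selection by the three biomarker criteria
  (proteotypic uniqueness against a background proteome, highest signal,
  cysteine-free), emitted as a Skyline-style transition-list CSV.
  Core ion arithmetic, for a peptide of monoisotopic neutral mass M:

      precursor m/z = (M + z·1.00728)/z
      y_i = (Σ C-terminal i residues + 18.010565 + z·1.00728)/z
      b_i = (Σ N-terminal i residues + z·1.00728)/z

* **Quantification** — internal-standard normalisation of long-format
  peak-area tables (`PA × IS_water/IS_sample`, correcting ionization-stage
  drift only), relative ATI content as total quantifier PA per mg flour via
  an explicit, overridable dilution chain, composition percentages, and
  matrix-effect recovery/loss for the digestion-monitor protein.

* **Validation** — ICH-style linearity (`y = a + bx` by OLS), `LOD = 3·Sa/b`,
  `LOQ = 10·Sa/b` with per-analyte units, intraday/interday %RSD, and IS
  recovery, assembled into a per-analyte report.

* **Simulation** — a generator with known ground truth that separates
  digestion-stage suppression (spares the IS) from ionization-stage drift
  (shared by all ions) plus lognormal replicate noise, so every analysis
  stage can be verified without an instrument. Protein-level descriptors
  (length, average MW, Bjellqvist pI) and global alignment identity
  statistics round out the toolbox.

## Worked example

```r
library(mrmati)

targets     <- synthetic_ati_proteins()        # 2 synthetic ATI-like chains
background  <- synthetic_background_proteins() # toy background proteome
intensities <- c(ELAAVPSR = 2e6, TYMVR = 1.5e6, IYAVSR = 1e6,
                 AGDSSLK = 9e5, VVDDAWK = 8e5)  # measured/simulated responses

method <- design_mrm_method(targets, background, intensities)
method$report
#>   accession n_candidates n_cys_free n_unique quantifier                  qualifiers
#> 1 SYN_ATI_A           12          6       11   ELAAVPSR              IYAVSR;VVDDAWK
#> 2 SYN_ATI_B           11          5       11      TYMVR AGDSSLK;ANWCEPGLVIPLNPLPSCR
```

Both quantifiers are cysteine-free and unique to their parent; the
cysteine-containing qualifier carries carbamidomethyl in its modified
sequence and masses. The first transitions of the list:

```r
head(method$transitions, 4)
#>     protein peptide_modified_sequence precursor_mz precursor_charge fragment_ion product_mz ...
#> 1 SYN_ATI_A                  ELAAVPSR     421.7402                2           y7   713.4304
#> 2 SYN_ATI_A                  ELAAVPSR     421.7402                2           y6   600.3464
#> 3 SYN_ATI_A                  ELAAVPSR     421.7402                2           y5   529.3093
#> 4 SYN_ATI_A                  ELAAVPSR     421.7402                2           y4   458.2722
```

421.7402 is the doubly protonated ELAAVPSR precursor; the product column
holds the singly charged y-ion m/z values computed from the residue table.
Quantifying a simulated 15-sample study (5% replicate CV, 3 replicates,
±4% ionization drift) after IS normalisation:

```r
cfg   <- default_scenario(seed = 7)
tab   <- simulate_measurements(cfg)
norm  <- is_normalize(tab, is_reference_area = cfg$is_true_area)
quant <- relative_ati_content(norm, cfg$proteins)
head(quant$summary[, 1:4])
#>   sample_id n_replicates total_pa_per_mg_mean total_pa_per_mg_sd
#> 1       S01            3             3732.282           297.2095
#> 2       S02            3             5571.096           537.9000
#> 3       S03            3             7631.892           414.2711
#> ...

recovery_experiment(cfg, n_runs = 50)
#> <parameter recovery> 50 runs x 15 samples
#> median |relative error| = 0.0242; mean Kendall tau = 1.0000
```

The estimated totals track the configured truth to a median 2.4% and
preserve the abundance ranking exactly — and the same experiment with
digestion-stage suppression shows the bias IS normalisation *cannot*
remove, which is why the workflow carries a digestion-monitor protein.

A command-line wrapper with `build-method`, `quantify`, `validate`,
`simulate` and `align` subcommands is installed at
`system.file("cli", "mrmati.R", package = "mrmati")`; example inputs live in
`inst/extdata/`.

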