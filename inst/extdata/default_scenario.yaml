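seed: 1
replicate_cv: 0.05
n_replicates: 3
is_true_area: 100000.0
blg_true_area: 500000.0
proteins:
  ATI_A: ELAAVPSR
  ATI_B: TYMVR
calibration:
  amounts:
  - 10.0
  - 25.0
  - 50.0
  - 100.0
  - 150.0
  - 200.0
  slope: 57.89999999999999858
  intercept: 100.0
  noise_sd: 150.0
  replicates: 3
  unit: pg
samples:
- sample_id: S01
  digestion_suppression: 1.0
  ionization_factor: 0.95999999999999996
  true_abundance:
    ELAAVPSR: 179.36000000000007049
    TYMVR: 124.64000000000005741
- sample_id: S02
  digestion_suppression: 1.0
  ionization_factor: 0.96571428571428564
  true_abundance:
    ELAAVPSR: 265.40966343276784301
    TYMVR: 167.15556218524727683
- sample_id: S03
  digestion_suppression: 1.0
  ionization_factor: 0.97142857142857142
  true_abundance:
    ELAAVPSR: 392.16284205182358846
    TYMVR: 223.33937641516413919
- sample_id: S04
  digestion_suppression: 1.0
  ionization_factor: 0.97714285714285709
  true_abundance:
    ELAAVPSR: 578.65717058175221155
    TYMVR: 297.14827678522414089
- sample_id: S05
  digestion_suppression: 1.0
  ionization_factor: 0.98285714285714287
  true_abundance:
    ELAAVPSR: 852.75276254322318437
    TYMVR: 393.44125369948295656
- sample_id: S06
  digestion_suppression: 1.0
  ionization_factor: 0.98857142857142855
  true_abundance:
    ELAAVPSR: 1255.18950666740556699
    TYMVR: 518.03482162156296909
- sample_id: S07
  digestion_suppression: 1.0
  ionization_factor: 0.99428571428571433
  true_abundance:
    ELAAVPSR: 1845.49818138386922328
    TYMVR: 677.64386347688946444
- sample_id: S08
  digestion_suppression: 1.0
  ionization_factor: 1.0
  true_abundance:
    ELAAVPSR: 2710.60772521587659867
    TYMVR: 879.60118235482082127
- sample_id: S09
  digestion_suppression: 1.0
  ionization_factor: 1.00571428571428578
  true_abundance:
    ELAAVPSR: 3977.37190664907620885
    TYMVR: 1131.179166111205177
- sample_id: S10
  digestion_suppression: 1.0
  ionization_factor: 1.01142857142857134
  true_abundance:
    ELAAVPSR: 5830.79106601545390731
    TYMVR: 1438.22718191120270603
- sample_id: S11
  digestion_suppression: 1.0
  ionization_factor: 1.01714285714285713
  true_abundance:
    ELAAVPSR: 8540.50550590191960509
    TYMVR: 1802.66725211078551183
- sample_id: S12
  digestion_suppression: 1.0
  ionization_factor: 1.02285714285714291
  true_abundance:
    ELAAVPSR: 12499.29784721948271908
    TYMVR: 2218.12602671430659029
- sample_id: S13
  digestion_suppression: 1.0
  ionization_factor: 1.02857142857142869
  true_abundance:
    ELAAVPSR: 18279.02335850778399617
    TYMVR: 2662.57459722944713576
- sample_id: S14
  digestion_suppression: 1.0
  ionization_factor: 1.03428571428571425
  true_abundance:
    ELAAVPSR: 26711.82293439655040856
    TYMVR: 3086.2265541733054306
- sample_id: S15
  digestion_suppression: 1.0
  ionization_factor: 1.04000000000000004
  true_abundance:
    ELAAVPSR: 39007.99999999998544808
    TYMVR: 3391.99999999999727152
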