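# eemdom

Fluorescence excitation–emission matrix (EEM) analysis of dissolved
organic matter (DOM), built for studies of algae-derived fluorescent DOM
(FDOM) in culture experiments: what fraction of the "terrestrial-looking"
humic fluorescence in natural waters could in fact be produced by the
algae themselves?

The package covers the full workflow a fluorescence spectroscopist runs
between the instrument export and the numbers in a results table:

1. **Preprocessing** — blank subtraction, absorbance-based (ABA)
   inner-filter correction `F' = F · 10^((A_ex + A_em)/2)`, normalization
   to Raman Units (R.U.) by the area of the water Raman band (371–428 nm
   at 350 nm excitation), excision of first/second-order Rayleigh and
   Raman scatter (±18 nm / ±30 nm, Raman shift 3400 cm⁻¹), interpolation
   of the excised gaps with a two-dimensional Whittaker smoother, and
   per-sample scaling by the standard deviation.
2. **Nonnegative PARAFAC** — the trilinear model
   `X[i,k,j] ≈ Σ_f a[i,f] · c[k,f] · b[j,f]` fitted by alternating
   nonnegative least squares (exact active-set solves per mode), with
   masked cells handled by expectation–maximization imputation.
   Emission/excitation loadings are normalized to unit maximum, so scores
   are the modeled peak intensities F_max in R.U.
3. **Validation** — split-half analysis on randomly partitioned sample
   halves with greedy component matching and Tucker congruence
   coefficients, plus the core-consistency diagnostic (CORCONDIA).
4. **Reporting** — spectral peak positions (with sub-grid apex
   refinement and boundary censoring, e.g. "≤250 nm"), classification
   against the conventional Coble fluorophores (B, T, A, C, M), and
   contribution accounting: per-sample percent shares, across-strain
   summaries, component intensity ratios and the contribution of the
   culture media themselves.
5. **Synthetic data** — a generator that emulates the culture study
   (three fluorophores, Rayleigh/Raman ridges, media blanks, instrument
   grid), with ground truth returned alongside, so every stage is
   testable without instrument files.

## Worked example

The package bundles the published component intensities (F_max, R.U.) of
five Arctic microalgae strain cultures at stationary phase and of the two
fresh cultivation media, so the contribution arithmetic can be reproduced
without any spectra:

```r
library(eemdom)
tab <- algal_fdom_intensities()
fmax <- as.matrix(tab[, c("C1", "C2", "C3")])
rownames(fmax) <- tab$sample
ct <- contribution_table(fmax, is_blank = tab$is_blank)
reproduce_table1_summary(ct)
```

```
Component intensities at the stationary phase (n = 5):
  C1: 0.146 R.U.; share 44 +/- 15 % (range 29-66 %)
  C2: 0.108 R.U.; share 29 +/- 14 % (range 11-48 %)
  C3: 0.086 R.U.; share 27 +/- 5 % (range 22-33 %)
  C1/C2 intensity ratio: 0.6-5.8
  Media contribution to the final signal (media not consumed): C1 3.8%, C2 2.8%, C3 9.3% 
```

Reading: the protein-like component C1 averages 0.146 R.U. and dominates
most strains (mean share 44%, up to 66%); the humic-like C2 reaches 48%
in one green-algae strain; the humic-like C3 contributes a consistent
22–33%. The fresh media account for only ~3–9% of the final signal, so
nearly all of the humic-like fluorescence was produced during algal
growth.

A full synthetic run of the spectral pipeline:

```r
sim <- simulate_dataset(default_scenario(seed = 7))
ds  <- preprocess_dataset(sim$dataset, sim$water_blank, downsample_emission = 4)
m   <- fit_parafac(ds, 3, fit_config(n_starts = 2, seed = 1, tol = 1e-6))
find_component_peaks(m, 1)
#> <component_spectrum> C1: ex 278.9 / em 329.4 nm -> Coble class T
compute_fmax(m, ds)   # per-sample intensities in R.U.
```

`run_pipeline()` drives all stages from one (YAML-able) configuration and
writes preprocessed EEMs, the model, the split-half report and the
contribution tables to an output directory.

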