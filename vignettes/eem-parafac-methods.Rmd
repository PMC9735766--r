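---
title: "EEM preprocessing and nonnegative PARAFAC: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEM preprocessing and nonnegative PARAFAC: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `eemdom`, the parameters that
matter, and the design decisions taken where practice leaves room — in
the spirit of the long methodological vignettes of packages like DESeq2
or vegan. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement and its corrections

An EEM is the fluorescence intensity $F(\lambda_{ex}, \lambda_{em})$ of
one sample on a rectangular wavelength grid. Before any multiway
modeling, four physical artifacts must be dealt with, in a fixed order
that the package enforces through a per-EEM stage tag:

1. **Blank subtraction** (optional, default on). The ultra-pure water
   blank measured alongside the samples is subtracted cellwise. Whether a
   study subtracts the blank or only uses it for Raman normalization
   varies between labs; both paths are supported
   (`preprocess_eem(blank_subtract =)`).

2. **Inner-filter correction.** Chromophores attenuate both the
   excitation beam and the emitted light. The absorbance-based (ABA)
   correction multiplies each cell by
   $10^{(A(\lambda_{ex}) + A(\lambda_{em}))/2}$, with $A$ the decadic
   absorbance per 1 cm path. ABA is the de-facto standard and what
   benchtop EEM instruments implement in their own software; more exact
   cell-geometry corrections differ by well under a percent at the
   absorbances (< 0.3) typical of culture filtrates. Negative absorbance
   readings (blank drift) are clamped to zero with a warning, so the
   correction can never shrink an intensity.

3. **Raman normalization.** Intensities are divided by the area under
   the water Raman band of the blank — emission 371–428 nm at 350 nm
   excitation, trapezoidal rule — giving Raman Units (R.U.). Only the
   excitation wavelength of this band is universal; the 371–428 nm
   integration window is the common convention and is configurable
   (`raman_band()`).

4. **Scatter handling.** First-order Rayleigh ($\lambda_{em} \approx
   \lambda_{ex}$) and Raman ($1/\lambda_{em} = 1/\lambda_{ex} -
   3400\,\mathrm{cm}^{-1}$) ridges and their second orders are not
   fluorescence and must be removed before trilinear modeling. Cells
   within ±18 nm of a first-order ridge and ±30 nm of a second-order
   ridge are excised. The anti-Stokes strip
   $18 < \lambda_{ex} - \lambda_{em} < 30$ nm is left *undefined*:
   excluded from everything downstream, never interpolated. The deeper
   non-physical triangle $\lambda_{ex} - \lambda_{em} \ge 30$ nm is set
   to zero and kept valid — see "Why the non-physical region is zero, not
   missing" below.

### Whittaker interpolation of the excised gaps

Excised cells are refilled by a penalized least-squares (Whittaker)
smoother over the whole excitation × emission plane:

$$\min_z \sum_{kj} w_{kj}(z_{kj} - y_{kj})^2 \;+\; \lambda\!\left(
  \lVert D^{(d)}_{em} z \rVert^2 + \lVert D^{(d)}_{ex} z \rVert^2\right),$$

with weights 0 on excised cells, differences of order $d = 2$ by default,
and $D^{(d)}$ built from *divided* differences so that $\lambda$ is in
physical (per-nm) units and transfers between instrument grids. The
system is sparse and solved exactly (Cholesky).

Smoothing in **two dimensions** is essential rather than cosmetic: the
water Raman ridge crosses the emission band of a protein-like (T-type)
fluorophore close to its apex. A one-dimensional fill along each emission
scan bridges *under* the peak, and we measured the resulting bias on the
fitted peak intensities at −17% for the protein component even on
noise-free synthetic data; the 2-D fill reduces this to ≲2% because the
unmasked neighboring excitation rows carry the band shape across the gap.

Rayleigh gaps (wide, diagonal, low local curvature) use a stiffer penalty
than Raman gaps: defaults $\lambda_{Rayleigh} = 10^3$,
$\lambda_{Raman} = 10^2$ in divided-difference units, chosen by measuring
fill fidelity against known synthetic truth (median fill error ≈ 1% in
the Raman gaps crossing emission bands, ≈ 3% over all filled cells
carrying more than 5% of the EEM maximum). In published workflows these
penalties are tuned by eye per instrument; both are exposed in
`scatter_config()`. Relative fill error remains large where the *absolute*
signal is near zero (cells deep inside the Rayleigh band next to the
undefined strip); such cells are a negligible share of the fitted
variance.

### Why the non-physical region is zero, not missing

Fluorescence cannot appear at emission wavelengths far below the
excitation wavelength. Two treatments of that triangle are seen in
practice: exclude it (missing data) or fix it at zero. We implement the
zero anchor, for an identifiability reason found during development: with
the triangle excluded, the excitation loading of a short-emission
fluorophore is unconstrained at high excitation — its entire emission
band falls in masked territory there — and EM imputation then freezes
whatever the random initialization placed in those coordinates. Symptoms
were spurious high-excitation loading plateaus and split-half congruences
collapsing to ~0.6 on data whose true structure was perfectly stable.
Anchoring the physically-zero region at zero removes the flat directions;
it is also what the intensity truly is there.

5. **SD scaling.** Each sample's valid cells are divided by their
   standard deviation (n−1, valid cells only) so bright cultures do not
   dominate the fit; the divisors are stored and folded back into the
   reported intensities by `compute_fmax()`.

## The trilinear model

PARAFAC decomposes the preprocessed cube (sample × excitation × emission)
as $X_{ikj} \approx \sum_f a_{if}\, c_{kf}\, b_{jf}$ with all factors
nonnegative. Each alternating-least-squares step solves its matricized
subproblem exactly with an active-set NNLS on the normal equations
(Gram matrices are tiny — $F \times F$), which keeps iterations
deterministic. Masked cells are replaced by the current model value
before each iteration (EM imputation), so the observed-cell SSE is
non-increasing; the per-iteration SSE trace is stored in the model and
asserted in the tests.

Choices that resolve the model's indeterminacies:

* **Scale**: emission and excitation loading columns are rescaled to unit
  maximum, magnitudes absorbed into the scores. A score is then the
  modeled peak intensity (F_max) of that component in that sample, in
  R.U. after unscaling.
* **Permutation**: components are ordered by ascending emission-peak
  wavelength, so two fits with the same seed are identical.
* **Initialization**: the first start is a deterministic nonnegative
  spectral start (absolute leading singular vectors of each mode
  unfolding); remaining starts are uniform(0,1) draws. The spectral start
  lands in the dominant basin nearly always; the random starts guard
  against its rare failures. The lowest-SSE start wins.
* **Convergence**: relative SSE change below `tol` (default $10^{-8}$) or
  `max_iter`. EM imputation converges linearly with a slow tail, so
  practical fits (the pipeline default) use `tol = 1e-6`; the loadings are
  unchanged to well beyond the quoted precision while iteration counts
  drop several-fold.

`corcondia()` computes the core-consistency diagnostic from the
least-squares Tucker core (masked cells imputed from the model): 100 on
exactly trilinear data, dropping sharply when over-factored.

## Split-half validation

`split_half()` draws `n_splits` (default 32) independent random
partitions of the samples into two halves (sizes differing by at most 1),
fits the candidate rank to each half, matches components greedily by the
product of excitation and emission Tucker congruences (ties broken by
emission-peak proximity), and validates the rank when the *minimum*
congruence over splits, components and both spectral modes reaches 0.95.
"N randomly-set halves" is read as N independent partitions (2N half
fits); the deterministic quarter-combination scheme some packages offer is
out of scope. A component that collapses to a zero loading in an
over-factored half-fit scores congruence 0, which correctly invalidates
that rank. Half-fits reuse the fit configuration with seeds derived from
the partition seed, so a reported result regenerates exactly.

## Component characterization and contribution accounting

Peak positions are reported with sub-grid apex refinement: a quadratic
fit to the log-loading over the contiguous near-apex window (exact for a
Gaussian band). This frees the reported position from the grid pitch —
on a 4–5 nm fitting grid the raw argmax is quantized by several nm, while
refined positions land within ~1 nm of the true band centers on synthetic
data. The raw grid argmax is retained (`wavelength_grid`, or
`refine = FALSE`). An excitation maximum on the first or last grid point
is flagged boundary-censored and printed as "≤λ"; the band likely
continues outside the measured range.

Coble classification uses the conventional windows on (excitation peak,
emission peak): T 270–290/320–360, B 265–285/295–320, A 230–275/380–480
(censored edge peaks count), C 320–380/420–490, M 285–320/370–420 nm.
With several excitation peaks the class is a majority vote over the
classified peaks, ties resolved by the primary peak.

Contribution accounting works on F_max: per-sample percent shares
(summing to 100), across-strain means, SDs (n−1) and ranges with media
blanks excluded, pairwise intensity-ratio ranges on request, and the
media's own contribution under the assumption that medium FDOM is not
consumed during cultivation: mean blank F_max divided by the across-strain
mean stationary F_max, per component. Display rounding is half-up at the
conventional printed precision; raw values are always retained.

## The synthetic-data generator

`default_scenario()` emulates a stationary-phase culture experiment:

* instrument grid — excitation 250–590 nm in 5 nm steps, emission
  260–800 nm in 1.12 nm steps;
* three fluorophores with Gaussian bands: protein-like T at 278/330 nm
  (σ 15/18 nm), humic-like C at 376/470 nm with a sub-300 nm excitation
  shoulder, humic-like A at 315/421 nm with a sub-260 nm excitation band
  whose apex is censored at the grid edge;
* 24 strain samples with per-component peak intensities drawn uniformly
  from 0.02–0.31 R.U. (the span of the published culture intensities) and
  3 media blanks with a fixed near-detection-limit background
  (0.0055/0.003/0.008 R.U.) — modeled as component-equivalent
  concentrations rather than a structured medium spectrum, since real
  media rows sit at the detection limit;
* Rayleigh ridges at $\lambda_{ex}$ and $2\lambda_{ex}$ (Gaussian
  cross-section, σ 5 nm; amplitudes 5 and 1 R.U.) and the water Raman
  ridge, whose amplitude is calibrated so the blank's Raman band area is
  exactly 1 — everything is then multiplied by `raw_scale` so the
  generator emits instrument-like raw units and Raman normalization has
  real work to do;
* additive homoscedastic Gaussian noise, default SD $5\times10^{-4}$
  R.U. A heteroscedastic option (SD proportional to signal) exists, off
  by default. The default noise floor is set so that the media blanks
  (0.002–0.008 R.U.) remain resolved measurements, as they are in
  published tables of this kind; a floor of $2\times10^{-3}$ R.U. would
  make medium EEMs pure noise, which mismatches how such tables are
  reported and, after SD scaling, lets blank-heavy split-half partitions
  fit noise components.

What the generator does **not** emulate: inner-filter distortion (the IFE
correction is tested against analytically constructed absorbance
instead), detector spectral bias, wavelength-dependent (heteroscedastic)
noise by default, drift, and non-Gaussian band shapes. Passing recovery
tests on this generator therefore demonstrates correctness of the
algorithms under the stated statistical assumptions, not robustness to
every artifact of real instruments.

## Problem sizes and numerical choices

The fits in the tests and in `scripts/acceptance.R` run on the emission
axis downsampled 4× (4.48 nm pitch, 121 points; split-half 8×) after
interpolation — at 15–40 nm bandwidths the loadings are heavily
oversampled at 1.12 nm, and alignment onto coarser grids is part of the
package's contract. Split-half uses 32 partitions with 2 starts and 300
iterations per half-fit; the main fits use 2 starts, `tol = 1e-6` and a
cap of 800 iterations. Degenerate inputs are handled explicitly: zero
Raman area, constant samples under SD scaling, all-zero loading vectors
in congruence, rows with no valid cells (left undefined with a warning),
flat loadings in peak picking (class "unknown"), and singular active sets
in NNLS (rank-revealing QR fallback).

## Known limitations

* EM imputation's slow convergence tail means `tol = 1e-8` is rarely
  reached within a practical iteration budget on noisy data; the
  `converged` flag and SSE trace are stored so users can judge.
* The 2-D Whittaker fill cannot reconstruct signal in regions where both
  axes are masked for tens of nm and the absolute signal is small;
  relative errors there are large (the affected variance is negligible).
* Split-half matching is greedy; with strongly overlapping components a
  globally optimal assignment could differ. For the well-separated
  fluorophores of this application the greedy match equals the optimal
  one.
* The Coble windows are hard conventions; fluorophores near window edges
  can flip class with small peak shifts.
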