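---
title: "Counting molecules in fluorescent particles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting molecules in fluorescent particles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smstoich)
```

# The measurement problem

Pro-apoptotic BAX and BAK permeabilize the mitochondrial outer membrane by
assembling into oligomers, and the two proteins do so differently: BAK forms
small assemblies that saturate quickly, while BAX keeps growing into large
foci. Resolving that difference requires counting protein copies inside
diffraction-limited fluorescent spots, which this package does along two
complementary routes:

1. **Brightness stoichiometry (in vitro regime).** On supported lipid
   bilayers, the integrated brightness of a particle is an integer multiple
   of the brightness of one fluorophore. A particle brightness distribution
   is therefore a mixture of `n` discrete components, and decomposing it
   yields the fraction of monomers, dimers, and higher n-mers.
2. **Ratiometric molecularity (in-cell regime).** In cells, absolute
   brightness is not portable across optics and days, so foci are compared
   against an internal standard of known copy number imaged under identical
   conditions: the nucleoporin Nup96, present in exactly 32 copies per
   nuclear pore complex and tagged with the same fluorophore. The molecule
   number of a focus is then `Mp = Ip * Ms / Is`.

Both routes share one detection core: difference-of-Gaussians candidate
search, isotropic 2D Gaussian fitting inside a small circular ROI with a
local background annulus, and quality filters (overlap, width percentile,
and -- for z-stacks -- discarding particles brightest in an outer plane).

# Spot detection and brightness extraction

## Detection

Candidates are strict local maxima of the DoG band-pass response above a
threshold. The threshold is deliberately exposed: no universal value exists
across detectors and illumination intensities. The default is a
noise-quantile rule, five robust standard deviations (MAD) of the response,
which on synthetic fields at peak SNR 5 gives precision and recall above
95%. Candidates closer than one PSF FWHM are deduplicated, strongest
response first.

## Fitting

Each candidate is fit with an isotropic Gaussian
`A * exp(-((r-r0)^2 + (c-c0)^2) / (2 sigma^2))` over the disc of radius 3 px
(2 px is the choice for the in-cell z-projections; both radii are
arguments). The local background `b` is the mean of the annulus between the
ROI radius and the background radius (4 px, respectively 3 px). Because the
PSF tail leaks into that annulus, using the raw annulus mean biases the
fitted volume low by roughly 10% at sigma = 1.3 px; the fit therefore
refines the background by subtracting the fitted model's annulus mean and
refitting, which converges in two to three rounds and is exact on noiseless
spots. Brightness is the fitted Gaussian volume `Ip = 2 pi A sigma^2`; a
model-free pixel-sum oracle over the full PSF support pins this identity in
the tests.

Coordinates are 1-based pixel centers, the R imaging convention; subpixel
positions are reported as floats. We store the Gaussian standard deviation
as the width; the field often quotes FWHM = 2.355 sigma.

## Quality filters

The width filter excludes ROIs whose sigma exceeds the per-image 95th
percentile of the sigma sample: an inflated width is the signature of two
or more particles sharing one ROI. It is one-sided -- narrow fits carry no
such risk -- and is skipped below 20 fits, where an empirical percentile is
meaningless. The overlap rule discards *both* members of any pair closer
than 7 px (ROI radius + background radius, so background annuli can never
intersect); the conservative both-members choice reflects that neither
brightness is trustworthy once annuli overlap. Each rule is evaluated on
the full input sample independently, making the retained set independent of
rule order; re-filtering a retained set is idempotent given the same
explicit width cut.

# Monomer calibration and n-mer decomposition

## Photobleaching step counting

The monomer brightness unit `mu1` comes from particles that photobleach in
a single step. Traces are smoothed with a running median (window 5 frames
by default) and segmented into plateaus by binary segmentation with a
BIC-style penalty `8 sigma^2 log(n)`, with sigma estimated robustly from
first differences. The documented resolution is plateaus of at least about
15 frames; the recovery property (95% correct step counts on simulated
three-step traces) is evaluated on traces whose ground-truth bleaching
events respect that resolution. Any level increase beyond the noise
tolerance flags the trace as re-brightening and rejects it, since
photobleaching is irreversible. `mu1` and `sigma1` are the mean and SD of
the single-step populations' initial plateau height above final baseline.

## Fixed-component mixture fit

Brightnesses are decomposed as `sum_j w_j Normal(j mu1, j sigma1^2)`: the
mean and variance of component j are those of a sum of j independent
emitters, so only the weights are free. They are estimated by maximum
likelihood on the raw values with a weights-only EM iteration -- fitting the
raw sample rather than a histogram removes bin-width sensitivity. A floor
of `0.05 mu1` on component SDs guards the degenerate `sigma1 = 0`
calibration. The default `max_n = 10` covers the oligomer orders seen in
bilayer reconstitutions.

## Partial-labeling correction

With labeling efficiency `p`, a true n-mer displays `j ~ Binomial(n, p)`
labeled subunits, and `j = 0` particles are invisible. The observable
operator is the binomial mixing matrix with each column conditioned on
visibility (`1 - (1-p)^n`); observed weights are corrected by inverting it
with non-negative least squares and renormalizing. The conditioned
(invisible-class renormalized) operator is the default because the fitted
weights describe the detected population; the unconditioned variant is
available via `renormalize_invisible = FALSE`. For `p >= 0.8` and orders up
to 6 the inversion round-trips any composition with total-variation error
far below 0.05; efficiencies at or below 75% -- outside the acceptance range
for labeling chemistry in these experiments -- trigger a warning.

# Ratiometric molecularity and kinetics

Per cell, the standard intensity `i_s` is the mean of a Gaussian fit to the
cell's standard-complex intensity distribution (computed as the maximum
likelihood Gaussian mean, with optional trimming, off by default); `I_s`
averages `i_s` over at least five cells, below which calibration is refused.
`to_molecularity()` is the exact linear map `Ip Ms / Is`; the ferritin
24-mer cross-check is simply this map evaluated at three quarters of the
standard intensity.

At each timepoint the average molecularity of a cell's foci is taken from a
least-squares fit of `A exp(-M / <M>)` to the complementary cumulative
(survival) count `C(M) = #{foci >= M}`. The survival form is chosen because
for it the exponential decay constant *is* the mean, making the estimator
scale-equivariant and directly interpretable; fits fall back to the sample
mean below 10 foci or for degenerate samples. Summaries per timepoint are
the fitted mean, foci per mitochondrial area, and the fraction of foci
above 200 and above 400 molecules (strict inequality). Time is aligned to
MOMP using Smac release as the reference; pre-MOMP frames are flagged and
dropped.

Expression level is total GFP signal divided by the pixel area of the
mitochondrial mask, segmented from the marker channel by Otsu's method
(threshold overridable).

# The synthetic-data generator

Every stage is validated by parameter recovery on synthetic data whose
ground truth is fully known. The generator emulates:

- **Particle fields**: uniformly placed subpixel centers (optional minimum
  separation), oligomer order drawn from configured weights, binomial
  labeling, per-fluorophore brightness `Normal(mu1, cv mu1)` truncated at
  zero, rendering as a sampled isotropic Gaussian PSF (sigma 1.3 px at
  100 nm pixels), uniform background, Poisson shot noise and Gaussian read
  noise. The PSF model matches the fitting model on purpose: oracle tests
  are then exact, and PSF-model mismatch is deliberately not a simulated
  degree of freedom. Invisible (j = 0) particles stay in the truth table.
- **Bleaching traces**: geometric per-frame bleaching per fluorophore,
  stepwise-decreasing staircases plus Gaussian noise; no blinking, which at
  tens-of-millisecond exposures does not affect step counting.
- **Standard cells**: per-complex intensities `Normal(Ms * unit, cv Ms *
  unit)` truncated at zero, five cells by default.
- **Foci time series**: a mean trajectory `M(t)` that either saturates,
  `plateau (1 - exp(-t/tau))` with `tau = plateau / rate`, or grows
  linearly, `rate * t`. The saturating defaults (plateau 200 molecules,
  initial rate 80/min, so tau = 2.5 min) emulate fast-saturating BAK-like
  foci; the linear regime with ~10 molecules/min and a growing focus count
  emulates BAX-like growth. These functional forms are the simplest ones
  consistent with "stable size" versus "unbounded growth"; real
  trajectories are known only graphically. Per-focus molecularity is drawn
  exponentially around `M(t)` scaled by a per-timepoint lognormal factor of
  CV 0.1: the exponential dispersion matches the decaying shape of
  per-cell foci intensity distributions and is the distribution for which
  the survival-fit estimator is exact, while the lognormal factor models
  cell-level measurement variability. Focus counts are Poisson with
  constant expectation after an initial 5-minute nucleation burst
  (saturating) or expectation growing linearly in time (linear), scaled by
  `foci_birth_rate * mito_area` to the few-hundred-foci-per-cell range.

What the generator does **not** emulate -- and what passing recovery tests
therefore do not demonstrate about real data: optical aberrations and PSF
anisotropy, camera gain structure beyond additive Gaussian read noise,
drift, fluorophore blinking and maturation, spatially structured (e.g.
mitochondrial) backgrounds, and focus-to-focus correlations over time
(foci are redrawn per timepoint, not tracked).

# Numerical choices and problem sizes

- Simulated fields for detection properties are 200 x 200 px with 60-200
  particles; mixture recovery uses 4,000 particles; labeling round-trips
  run 25 random simplices per efficiency; survival fits use 5,000 draws;
  kinetic recovery uses thirteen 5-minute timepoints over an hour with a
  few hundred foci per timepoint. These sizes put Monte Carlo error well
  below each documented tolerance while keeping the whole suite at about a
  minute and a half of CPU.
- Trajectory recovery is judged at the trajectory level -- the plateau
  estimate (mean fitted molecularity over the saturated phase) and the
  fitted linear slope -- because per-timepoint estimates fluctuate with the
  modeled cell-level noise by construction.
- Ties in the max projection argmax resolve to the lowest plane;
  edge-frame discarding then behaves deterministically on constant stacks.
- All generators consume a single integer seed; identical configurations
  and seeds reproduce truth tables bit for bit.
- Detection performance criteria are evaluated on fields with a minimum
  center separation of 4 PSF sigma: closer pairs are unresolvable by any
  single-emitter fitter and are the business of the width/overlap filters,
  not of the detector.

# Known limitations

- The mixture decomposition assumes i.i.d. additive emitters; protein
  environments that alter fluorophore brightness with oligomeric state
  would bias high orders.
- The labeling inversion is ill-conditioned as p drops toward 0.5; we warn
  below the 75% acceptance threshold rather than refuse.
- The survival-fit mean is exact for exponential foci distributions;
  strongly non-exponential distributions (e.g. tightly sized assemblies
  with small spread) make it a shape-dependent effective mean. The
  fallback to the sample mean covers small or degenerate samples only.
- GUV analysis quantifies given vesicle centers and radii; vesicle
  segmentation is out of scope, and the 0.5 inside/outside permeabilization
  threshold is a configurable convention.
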