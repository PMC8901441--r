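# smstoich

Single-molecule brightness stoichiometry and oligomerization kinetics for
fluorescence microscopy.

## What problem this solves

Apoptotic effector proteins such as BAX and BAK assemble into oligomers on
the mitochondrial outer membrane, and the *size* of those assemblies — a
handful of protomers on a bilayer, or hundreds of molecules in a cellular
focus — is the quantity that distinguishes their mechanisms. `smstoich`
implements the two standard single-molecule counting strategies for this
regime, for anyone quantifying subunit copy numbers in diffraction-limited
spots:

- **Brightness stoichiometry.** A particle containing `j` fluorophores is
  `j` times as bright as one. Given a monomer brightness calibration
  (μ₁, σ₁) from single-bleaching-step particles, a brightness sample is
  decomposed by maximum likelihood into the mixture
  Σⱼ wⱼ·N(j·μ₁, j·σ₁²), and the observed labeled-unit fractions wⱼ are
  corrected for partial labeling efficiency `p` by inverting the binomial
  operator wⱼ ∝ Σₙ vₙ·C(n,j)·pʲ(1−p)ⁿ⁻ʲ (the invisible j = 0 class
  renormalized out), yielding true n-mer fractions vₙ.
- **Ratiometric molecularity.** In cells, a focus of intensity Iₚ is
  compared against an internal standard of known stoichiometry Mₛ and
  pooled intensity Iₛ (the 32-mer nucleoporin Nup96 tagged with the same
  fluorophore): **Mₚ = Iₚ·Mₛ/Iₛ**. Per-timepoint foci populations are
  summarized by an exponential fit of the survival count
  C(M) = #{foci ≥ M} (whose decay constant is the mean molecularity),
  foci per mitochondrial area, and the fraction of foci above 200 / 400
  molecules, on a clock aligned to MOMP (Smac release).

Around these sit a detection core (difference-of-Gaussians candidates,
two-pass 2D Gaussian fitting with annulus background and PSF-consensus
width, overlap/width-percentile/edge-frame quality filters), photobleaching
step counting, GUV radial-profile quantification, and a synthetic-data
module that generates image stacks, bleaching traces, standard cells and
foci time series with known ground truth, so every stage is testable by
parameter recovery. See the vignette in `vignettes/` for the methods and
design rationale.

## Worked example

Simulate a supported-lipid-bilayer-style field of 600 particles (30%
monomer / 70% dimer, 84% labeling efficiency), detect and fit spots,
calibrate the monomer unit from 200 bleaching traces, and decompose the
brightness distribution:

```r
library(smstoich)

cfg <- sim_config(field_size_px = c(400L, 400L), n_particles = 600L,
                  nmer_weights = c("1" = 0.3, "2" = 0.7),
                  labeling_efficiency = 0.84, min_separation_px = 8,
                  seed = 42L)
field <- generate_particle_field(cfg)
img   <- get_frame(field$stack, 1)
fits  <- fit_particles(img, detect_spots(img))
flt   <- filter_particles(fits)

traces <- generate_bleach_traces(1, 200, 0.03, 150, 8, seed = 43L,
                                 monomer_intensity = 500, monomer_cv = 0.15)
calib <- calibrate_monomer(traces$traces)
fit_gaussian_mixture(flt$retained$brightness, calib,
                     labeling_efficiency = 0.84)
```

```
<monomer_calibration> mu1 = 503.84, sigma1 = 82.43 counts (n = 192)
<mixture_result> n = 501 particles, mu1 = 503.84, logLik = -3393.7
  observed labeled-unit weights (%):
  1:43.0  2:57.0  3:0.0  4:0.0  5:0.0  6:0.0  7:0.0  8:0.0  9:0.0  10:0.0
  corrected n-mer weights (p = 0.84) (%):
  1:21.3  2:78.7  3:0.0  4:0.0  5:0.0  6:0.0  7:0.0  8:0.0  9:0.0  10:0.0
```

The monomer unit is recovered at 503.8 counts (truth 500). Among *detected*
particles the labeled-unit classes split 43% / 57% between one and two
fluorophores, and labeling correction attributes 79% of particles to
dimers. The corrected monomer fraction (21%) sits below the simulated 30%
because the dimmest single-fluorophore particles fall under the detection
threshold — the same completeness limit that applies to real data.

The ratiometric route, with a synthetic 32-mer standard:

```r
cells <- generate_standard_cells(Ms = 32, n_cells = 5, seed = 44L)
std <- calibrate_standard(cells, Ms = 32)
to_molecularity(std$I_s, std)          # 32  (a focus at standard intensity)
to_molecularity(0.75 * std$I_s, std)   # 24  (the ferritin 24-mer cross-check)
```

```
<standard_calibration> I_s = 3194.09 counts (Ms = 32, 5 cells)
```

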