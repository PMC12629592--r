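# TipKinetics

Single-molecule TIRF analysis of protein binding at growing microtubule
plus ends, in R.

Kinesin-13 depolymerases such as MCAK, end-binding proteins and
XMAP215-family polymerases all concentrate at the ~160 nm tip region of a
growing microtubule. Quantifying *how* — per-tubulin-dimer on-rates at the
end versus the lattice, dwell-time off-rates, per-site and multivalent
dissociation constants, and the split between direct end-binding and
one-dimensional lattice diffusion to the tip — takes a pipeline of
estimators applied to fluorescence movies. TipKinetics implements that
pipeline end to end, together with a ground-truthed synthetic TIRF
generator, so every stage is verifiable without any external data.

## What it computes

- **Localization** — microtubule end edges by a PSF-convolved step (erfc)
  model, `fitEndProfile()`; molecule peaks by Gaussian fits,
  `fitMoleculePeak()`; tip-relative event positions averaged over the
  dwell, `localizeEvent()`; binding-region FWHM from Gaussian or
  exponentially-modified-Gaussian distribution fits,
  `fitPositionDistribution()` (Gaussian FWHM = 2√(2 ln 2) σ);
  two-color offsets, `twoColorDistance()`; PSF widths from bead stacks and
  exact quadrature deconvolution of localization precision,
  σ_I² = σ_O² + σ_PSF² (`estimatePsfSigma()`, `deconvolvePrecision()`).
- **Kinetics** — single-dimer intensity gating (μ ± 2σ, closed interval),
  dwell-floor filtering, end/lattice classification, per-dimer on-rates
  k_on = events/(sites · time · concentration), the end/lattice
  selectivity R_E/L as mean of per-microtubule ratios,
  single-exponential dwell fits plus the shifted-exponential MLE that
  undoes the detection-floor truncation, K_d = k_off/k_on per dimer, and
  the multivalent effective K_d = K_d/N of an N-site end region.
- **Diffusion** — ensemble MSD with per-lag SEMs, D from ⟨x²⟩ = 2Dt over
  the first 4 lags, the scanned length √(2Dτ), and the Fick's-law flux of
  lattice-bound molecules onto the end, J₀ = D·c∞/x₀ with
  x₀ = √(D/k_off) and c∞ = (k_on·C/k_off)·ρ, cross-checked against a
  brute-force Brownian-walker simulation.
- **Dynamics** — growth-segment extraction from end traces, gamma
  lifetime MLE, and the probability-based catastrophe frequency
  (catastrophes per microtubules-at-risk per lifetime bin), with exact
  hazard→survival reconstruction.
- **Lattice intensity** — sum projections, background-subtracted
  per-micron intensities, paired condition ratios (e.g. GTPγS vs GDP
  lattices) and 3-pixel end/lattice ratios on stabilized microtubules.
- **Synthetic data** — gamma-lifetime dynamic microtubules, Poisson
  binding arrivals with exponential dwells, 1D Brownian lattice motion,
  photon-conserving PSF rendering with Poisson shot + Gaussian read
  noise, dwell samples, trajectories and bead stacks; bit-identical
  under a fixed seed. Movies round-trip through multi-page TIFF (+ JSON
  sidecar), events through versioned CSV, configs through YAML.

## Worked example

The flux model, evaluated at the measured kinetics of GFP-MCAK on dynamic
microtubules (D = 0.023 µm²/s, k_on-L = 2.8×10⁻⁶ s⁻¹ nM⁻¹ per dimer,
C = 10 nM, k_off-L = k_on-L × K_d-L with K_d-L = 1057 µM, 1625 dimers/µm):

```r
library(TipKinetics)

koffL <- 2.8e-6 * 1057e3                     # 2.96 s^-1
m <- fluxModel(D = 0.023, konLattice = 2.8e-6, koffLattice = koffL,
               concentration = 10, siteDensity = 1625)
#> x0 = 88.2 nm, c_inf = 0.0154 um^-1, J0 = 0.0040 s^-1

scannedLength(0.023, 0.6)                    # 166 nm scanned per lattice dwell
effectiveKd(computeKd(1.56, 22.6e-6), siteCount(160))
#> 265 nM: a 69 uM per-dimer Kd over the 260 dimer sites of a 160 nm end

directArrivalRate(22.6e-6, 10, 260)          # 0.059 s^-1 direct arrivals
diffusionContribution(m$J0_per_s, 0.067)     # 6.0 % via lattice diffusion
```

Reading: a lattice-bound molecule scans only ~one cap length before
unbinding, the diffusive flux onto the end (0.004 s⁻¹) is ~6% of the
observed arrival rate — end binding is dominated by direct arrivals from
solution — and although the per-dimer end affinity is weak (69 µM), the
260-site end region behaves as a ~265 nM multivalent receptor.

Estimator recovery on synthetic data with known truth:

```r
d <- simulateDwellSamples(0.75, 966, seed = 1)
fitDwellOffRate(d)
#> dwell: mean = 0.769 s, koff(fit) = 1.20 s^-1, koff(MLE) = 1.30 s^-1

set.seed(2)
tr <- simulateTrajectories(0.023, 203, nFrames = sample(4:60, 203, TRUE),
                           dt = 0.1, seed = 3)
fitDiffusionCoefficient(computeMSD(tr, 4))
#> D = 0.0244 +/- 0.0015 um^2/s
```

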