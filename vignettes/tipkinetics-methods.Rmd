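---
title: "Measuring single-molecule binding kinetics at growing microtubule ends"
author: "TipKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-molecule binding kinetics at growing microtubule ends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TipKinetics)
```

## The measurement problem

Microtubule-associated proteins such as the kinesin-13 depolymerase MCAK
reach growing plus ends either directly from solution or by binding the
lattice and diffusing one-dimensionally to the tip. Distinguishing these
pathways, and quantifying how much more avidly a protein binds the end
region than the lattice, requires a chain of estimators applied to
single-molecule TIRF movies:

1. sub-pixel localization of the microtubule end edge and of each
   molecule's intensity peak, frame by frame;
2. gating of candidate events to genuine single molecules by fluorescence
   intensity, and a dwell-time floor to suppress spurious detections;
3. per-dimer on-rates, dwell-time (off-rate) fits and dissociation
   constants per region;
4. mean-squared-displacement (MSD) estimation of the lattice diffusion
   coefficient, and a Fick's-law model that converts lattice kinetics into
   a diffusive flux onto the end;
5. microtubule lifetime statistics: gamma fits and a probability-based
   catastrophe frequency (a discrete hazard).

None of the raw imaging data behind these quantities are deposited
anywhere, so the package ships a ground-truthed synthetic TIRF generator:
every estimator can be validated against data whose true parameters are
known, and the published worked examples can be reproduced from the
published parameter values alone.

## End and molecule localization

**End edge (erfc model).** A microtubule imaged through a microscope with
a Gaussian point-spread function (PSF) of width $\sigma$ appears, along
its axis, as a step convolved with the PSF. We model the axial profile as

$$I(x) = bg + A\,\Phi\!\left(\frac{x_e - x}{\sigma}\right),$$

with $\Phi$ the standard normal CDF — equivalently an erfc profile. This
is the "Gaussian wall plus half-Gaussian end" picture in a single
continuous model: the half-maximum point $x_e$ coincides with the peak of
the half-Gaussian end component and serves as the end reference. We chose
the single-erfc formulation over separate wall and end terms because it
has fewer free parameters and its centre is exactly the quantity the
downstream analysis needs; whether the original fit shared a background
between components is not decidable from the published description.

Numerical choices: background initialised at the profile minimum,
amplitude at max − min, the edge at the half-maximum crossing; bounded
Levenberg–Marquardt least squares (`minpack.lm`). The fit is windowed to
±8 PSF widths around the distal-most falling edge so that a profile that
also contains the opposite microtubule end cannot distort the monotone
model. Weights default to inverse intensity ($1/I$, the shot-noise
variance): in simulation, unweighted least squares acquires a small
(≈2 nm) proximal bias because the bright lattice side is noisier in
absolute terms, and the weighting removes it. On noise-free profiles the
weighted fit can encounter a zero-residual singular gradient, in which
case the routine falls back to an unweighted fit (whose answer is then
exact anyway). Fits that fail or park the edge on the span boundary are
flagged and excluded downstream rather than guessed.

**Molecule peak.** A Gaussian plus constant background. Profiles with two
comparable local maxima (second ≥ 80% of the first above background) are
flagged ambiguous; flat profiles are flagged outright.

**Event position.** Per frame, the tip-relative position is peak minus
edge, distal positive (a negative position is proximal of the tip, on the
lattice side). The event position is the arithmetic mean over the dwell,
and events with fewer than two valid frames — the 200 ms detection floor
at 100 ms/frame — are rejected. The position is invariant under common
translation of peak and edge, which the tests assert.

**Binding-region width.** Pooled event positions are binned (20 nm
default) into a probability distribution and fitted with a Gaussian; the
full width at half maximum is $2\sqrt{2\ln 2}\,\sigma \approx 2.3548\,
\sigma$ exactly, and the binding region is $[\mu - \mathrm{FWHM}/2,\,
\mu + \mathrm{FWHM}/2]$. Binned least squares (not unbinned MLE) was
retained deliberately to match the probability-distribution fitting
convention of the original analysis; its FWHM sampling SD at $n = 152$
and 20 nm bins is about 15 nm (versus 9.4 nm for the moment estimator), a
variance cost we accept for fidelity to the published procedure. EB-cap
style comet distributions use an exponentially modified Gaussian (EMG)
whose tail direction is configurable (proximal/"negative" by default);
its FWHM has no closed form and is computed on a dense grid with
root-refined half-maximum crossings, which the tests pin to an
independent grid evaluation within 0.1 nm.

**Two-color distances.** With channel A as origin, per-frame distance is
$x_B - x_A$ plus an optional registration offset (zero by default; a
bead-derived offset may be supplied). Events contribute their dwell-mean,
and the modal distance is the centre of a Gaussian fitted to the binned
distribution.

**Localization precision.** The observed width of an imaged object is the
quadrature sum of the measurement error and the PSF width,
$\sigma_I^2 = \sigma_O^2 + \sigma_{PSF}^2$; `deconvolvePrecision()`
inverts this exactly, flags noise-dominated records
($\sigma_I < \sigma_{PSF}$) and reports their count. $\sigma_{PSF}$ comes
from stationary 100 nm multicolour beads: per-bead Gaussian fits to the x
and y marginals, corrected for pixel-box integration (a pixel of width
$p$ adds $p^2/12$ to the fitted variance), median across beads, with a
crowding guard that skips beads with a near neighbour. The population
precision is the SD of a Gaussian fitted to the distribution of per-event
mean errors.

## Single-molecule gating and kinetics

**Intensity gate.** A Gaussian is fitted to the probability distribution
of event mean intensities and events within $\mu \pm 2\sigma$ (closed
interval) are accepted as single dimers; on a pure Gaussian population
this accepts $\Phi(2)-\Phi(-2) \approx 95.45\%$. If the histogram is
bimodal (a second mode above 25% of the main one, e.g. a monomer
population), the fit is restricted to the dominant mode's side of the
valley and a warning is raised.

**Dwell floor.** Events must outlast 2 kymograph pixels (~200 ms at
100 ms/frame). Because exponential dwells are memoryless, conditioning on
exceeding a floor $t_0$ shifts the observed mean to $t_0 + \tau$; the
shifted-exponential MLE $\hat\tau = \bar t - t_0$ undoes this exactly and
is reported alongside the conventional binned single-exponential fit of
the dwell probability distribution. The exponential-fit rate is the
package's $k_{off}$ of record (it is the convention behind the published
dissociation constants, which are not consistent with $1/\bar t$); both
are always returned.

**On-rates and $R_{E/L}$.** $k_{on}$ is events per tubulin dimer per
second per nM. Site bookkeeping assumes 13 protofilaments and an 8 nm
axial dimer repeat (1625 dimers/µm; a 160 nm end region holds 260 sites),
both configurable. The end/lattice selectivity $R_{E/L}$ is the **mean of
per-microtubule ratios** with its SEM. This estimator is convex in the
lattice rate, so on finite per-microtubule counts it exceeds the ratio of
mean rates (Jensen's inequality) — which is exactly the relationship
between the published per-microtubule $R_{E/L}$ and the ratio one would
compute from the published mean rates. Both statistics are reported, and
a simulation test confirms the mean-of-ratios converges to the true ratio
as per-microtubule counts grow.

**Dissociation constants.** $K_d = k_{off}/k_{on}$ per dimer (µM).
Treating the end region as a multivalent receptor with $N$ independent
dimer sites, the effective constant is $K_d/N$ (the concentration at
which one molecule is expected bound; a brute-force occupancy solve
agrees within 1% for $N \ge 100$). The alternative half-occupancy
definition $K_d \ln 2 / N$ is provided but is not the default, because
the first-arrival form is the one consistent with the published
nanomolar figure.

## Lattice diffusion and the flux model

**MSD.** Time-averaged squared displacements per trajectory,
ensemble-averaged across trajectories, SEM over trajectories. The
diffusion coefficient is the slope/2 of an unweighted linear regression
over the first 4 lags with a free intercept — the intercept absorbs
static localization error, and 4 lags suits the short-track regime (the
minimum track length is 4 frames, 400 ms at 100 ms/frame). The standard
error of $D$ is propagated from the per-lag ensemble SEMs rather than
taken from the regression residuals, which are meaningless with few
nearly-collinear lags.

**Fick's-law delivery.** With lattice binding at $k_{on}C$ per site,
unbinding at $k_{off}$ and diffusion $D$, the steady-state lattice
concentration relaxes to $c_\infty = (k_{on}C/k_{off})\,\rho$ (site
occupancy × linear site density) over the decay length
$x_0 = \sqrt{D/k_{off}}$, and the flux into an absorbing end is

$$J_0 = D\,c_\infty / x_0 = c_\infty \sqrt{D\,k_{off}}.$$

The $k_{off}$ used here defaults to the exponential-fit convention
($k_{on} \times K_d$), which is what reproduces the published flux. The
closed form is cross-checked against an independent brute-force
simulation: walkers bind Poisson-uniformly on a lattice segment, take
Brownian steps (with the exact Brownian-bridge within-step absorption
probability $e^{-x_1 x_2 / (D\,\Delta t)}$, removing first-passage
discretization bias), unbind after exponential dwells, and the absorbed
fraction times the binding rate estimates $J_0$. Because flux is linear
in concentration, the simulation is run at whatever event count gives the
Monte-Carlo error the test needs. The diffusive contribution to
end-binding is $100\,J_0/N_p$ with $N_p = k_{on}C N_{sites}$ the direct
arrival rate. The published arrival rate corresponds to slightly more
end sites (~296) than the 260 of a 160 nm window — possibly a wider
empirical end region — so both the printed rate and the 260-site rate
are computed; the contribution percentage quoted against the printed
$N_p$ is the headline number.

## Microtubule lifetimes and catastrophe hazard

Growth segments are extracted from end-position traces wherever the slope
sign changes and persists for ≥3 frames; each yields a least-squares
growth rate and a lifetime, censored if the movie (not a catastrophe)
ended it. Lifetimes are fitted by maximum-likelihood gamma (shape ×
scale = mean); censored observations are excluded from the density fit —
matching a plain distribution fit, with the count reported — but are
handled correctly in the hazard's at-risk counts. The probability-based
catastrophe frequency in lifetime bin $b$ is the number of catastrophes
in $b$ over the number of microtubules that reached $b$'s start (30 s
bins by default). Two structural identities anchor this estimator:
exponential lifetimes give a flat hazard $1 - e^{-\Delta/\tau}$, and the
running product of $(1-f_b)$ telescopes exactly to the empirical survival
on uncensored data.

## The synthetic generator

`simulateDynamics`, `simulateBinding`, `renderMovie`,
`simulateDwellSamples`, `simulateTrajectories` and `renderBeadStack`
produce data with precisely the statistical structure the estimators
assume: gamma lifetimes with movie-end censoring flagged; Poisson
arrivals at rate $k_{on} C N_{sites}$ per region with the end window
tracking the moving tip; exponential dwells (optionally left-truncated at
the detection floor); lattice Brownian motion with increment variance
$2D\Delta t$; pixel-integrated Gaussian emitters and an erf-edged line
source for the microtubule (photon-conserving before noise: a noiseless
frame sums to background × pixels + total emitter brightness); Poisson
shot noise then Gaussian read noise; identical seed and configuration
give bit-identical pixels.

Defaults are the study conditions: 100 ms frames with 50 ms exposure,
0.75 s end and 0.62 s lattice dwells, $k_{on}$ of 22.6 and
2.8 × 10⁻⁶ s⁻¹ nM⁻¹ per dimer, $D = 0.023$ µm² s⁻¹, 10 nM molecules,
0.8 µm min⁻¹ growth, and a mean lifetime of 323 s (shape 3 by default —
the published distribution is clearly peaked, i.e. non-exponential, and
shape 3 with scale 107.8 s matches the published mean; the shape itself
is a simulation choice, not a published number). The camera pixel
(160 nm) and the single-molecule photon budget are not published either;
160 nm is typical of a 100× EMCCD TIRF setup and the synthetic
signal-to-noise is matched qualitatively, not to the instrument. The
kymograph "2 pixels ≈ 200 ms" dwell floor refers to the time axis and is
honoured independently of spatial pixel size.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no 3D or aberrated PSF, no EM-gain noise model
beyond a scale factor plus read noise, no photobleaching (dwell truth is
purely kinetic, as the original analysis applied no bleaching
correction), no shrinking-end rendering (catastrophe is instantaneous
disappearance; the analysis consumes growth phases and lifetimes only),
no helical/2D lattice diffusion, and microtubules are rendered along the
image x-axis (the analysis consumes 1D profiles, so orientation
generality would add nothing testable — polyline ROIs are still
supported).

## Interfaces and degenerate inputs

Movies round-trip through multi-page 32-bit-float TIFF with a JSON
sidecar (scale, calibration, channel layout); event tables are CSV with a
versioned schema line and row-indexed malformedness errors; configs
round-trip through YAML. Internally coordinates are 0-based pixel
indices; every reported position is physical (nm). Degenerate inputs fail
loudly rather than silently: non-positive rates, ROIs off the field,
fewer than 30 dwells or positions, all-equal lifetimes, a flat peak
profile, all-excluded ratio sets.

## Problem sizes

The validation suite uses the published sample sizes where they are part
of the worked examples (966 dwells, 203 trajectories, 152 positions, 62
two-color events, 66 microtubules, n = 400–443 lifetimes) and scales
Monte-Carlo checks (walker flux, hazard oracles, gate acceptance) to a
few × 10⁴–10⁵ draws, which keeps every statistical assertion at ≥3
standard errors while the whole suite runs in well under a minute.

## Known limitations

- The end-region classification uses the pooled Gaussian binding-region
  bounds, not per-event uncertainty; events beyond the tip are counted as
  end binding by convention.
- The 3-pixel end-window direction for stabilized-microtubule intensity
  ratios is ambiguous in the source description; tip-ward from the edge
  midpoint is the default and the lattice-ward variant is implemented.
- The gamma lifetime fit ignores censoring (matching the original plain
  density fit); with heavy censoring it will understate the mean, which
  the reported censored counts make visible.
- Dwell-time truth contains no photobleaching, so on real data the
  apparent off-rates fold in the bleaching rate.
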