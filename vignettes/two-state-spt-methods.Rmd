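---
title: "Two-state binding kinetics from fast sptPALM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state binding kinetics from fast sptPALM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptKinetics)
```

## The problem

A translation factor such as EF-P alternates between two diffusive
states in a living bacterium: a free state that explores the cytoplasm
rapidly (`D_fast`, several µm²/s) and a transient ribosome-bound state
that moves with the translating ribosome (`D_slow` ≈ 0.2 µm²/s). At
2 ms/frame, single-particle tracking PALM resolves individual
displacement steps, but localization error (σ ≈ 50–90 nm per
coordinate) and confinement inside the ~0.9 µm-wide spherocylindrical
cell distort every analytic expectation. The package therefore takes
the simulation-based route: every model quantity — the single-step
displacement distribution P(r), the six-step mean distribution
P(⟨r⟩₆), the MSD — is obtained by forward-simulating the full
observation process and compared to data with a reduced chi-square.

The kinetic model (`TwoStateModel`) has five core parameters:

| parameter | meaning | unit | typical value |
|---|---|---|---|
| `Dslow` | bound-state diffusion coefficient | µm²/s | 0.2 |
| `Dfast` | free-state diffusion coefficient | µm²/s | 4.3 |
| `fSlow` | stationary bound fraction | — | 0.30 |
| `tauFree` | mean free dwell (1/binding rate) | ms | 16 |
| `tauBound` | mean bound dwell (1/dissociation rate) | ms | 7 |

plus per-state dynamic localization errors `sigmaSlow`/`sigmaFast`
(nm, per coordinate). With exchange enabled the bound fraction is not
free: `fSlow = tauBound/(tauBound + tauFree)`, and the constructor
enforces this to 1e-9.

## Forward simulator

`simulateEnsemble()` integrates 3D Brownian motion inside a
`Spherocylinder` at 20 substeps per 2 ms frame (0.1 ms; the rms
substep of even a 10 µm²/s walker is ~45 nm, far below the 450 nm cap
radius). State switching uses exact exponential dwell sampling
(event-driven), applied at substep resolution; the observed frame
position is the mean of the substep positions within the exposure
(motion blur) projected to (x, y), plus Gaussian noise with the σ of
the frame's majority-occupancy state. A frame split exactly 50/50
takes the state at its first substep. `blur = FALSE` replaces the
exposure average by the instantaneous frame-start position, which makes
the free-diffusion closed form exact — the per-axis displacement
variance is then 2DΔt + 2σ², the basis of several oracle tests.

σ is interpreted as a **per-coordinate** standard deviation. If a data
source quotes the 2D radial rms instead, divide by √2 before passing
it in.

**Confinement.** A substep proposal that leaves the cell is rejected
and the walker keeps its position for that substep (Metropolis-style
rejection with a symmetric proposal). This preserves the uniform
equilibrium distribution exactly. The seemingly natural alternative —
redrawing the Gaussian step until the endpoint lands inside — does
not: the stationary density of that chain is proportional to the
in-domain proposal mass, which is depleted within about one step
length of the wall (~30% at step/width ≈ 0.15 in a 1D check). The
uniform-null axial comparisons below are only valid because of this
choice.

**Seeding.** Each trajectory runs on its own counter-based
xoshiro256++ stream derived from (master seed, trajectory index), so
ensembles are bit-for-bit reproducible and a prefix of a larger
ensemble equals the smaller one.

## Summary statistics

Trajectories shorter than 7 localizations are dropped
(`filterByLength`); a 7-frame trajectory yields exactly six steps.
P(r) pools all consecutive-frame displacements; P(⟨r⟩₆) takes one
value per trajectory, the mean of its first six steps. Default
binning is 25 nm on [0, 1.2] µm for P(r) and [0, 0.8] µm for P(⟨r⟩₆)
(~60 nm localization error makes finer bins noise-dominated); overflow
accumulates in the last bin so counts are conserved. `msdCurve`
truncates trajectories to six steps by default and reports the SEM of
the squared displacements per lag ("±1σ of the MSD values" admits
either reading; a population-SD flag is exposed). `dSigmaFromMsd`
inverts the line through the first two MSD points: D = slope/4,
σ = √(intercept/4), with negative intercepts clamped to σ = 0 and
flagged.

Axial analysis scales cell-frame axial positions by the cell length to
[−0.5, 0.5]; cells are first sorted into 1-µm length windows
(`lengthRange`). Localizations outside the nominal cell (possible with
noise) are rejected with a warning count, not clipped. The "no
binding" null is the closed-form projection of the uniform density
(`uniformAxialProfile`): cross-section πr² along the body,
π(r² − (|x| − a)²) across the caps, integrated per bin. When testing a
pooled distribution against this null, note that localizations within
one trajectory are strongly autocorrelated; the tests use one
localization per trajectory so that multinomial chi-square scaling
applies.

## Fitting

`buildModelLibrary` simulates a static single-state ensemble for each
(D, σ) on a log-spaced D grid (default 0.05–20 µm²/s, 25
points/decade) in the target geometry and bins it exactly like the
data; each entry holds ≥ 10,000 steps (60,000 in the shipped
configurations). The static fit is an exhaustive grid search of
`f_slow · P(r; D_slow, σ_slow) + (1 − f_slow) · P(r; D_fast, σ_fast)`
with f on a 0.05 grid, `D_slow ≤ D_fast` enforced, ties broken toward
smaller `D_fast` then smaller `f_slow`, and constraints (e.g.
`D_slow = 0.2` fixed to the ribosome value) snapping to the nearest
library grid point. σ values are inputs — taken from MSD intercepts or
imaging calibration — not free parameters, matching how they are
reported per component in the source analyses. Grid, not gradient,
because the objective is itself a noisy simulation.

**Chi-square.** For two binned, normalized histograms the statistic is
χ² = Σ (p_exp − p_model)²/s² with s² = p̄(1/n_exp + 1/n_model), the
Poisson error of both histograms evaluated at the pooled proportion
p̄. Runs of bins where both histograms hold fewer than 5 counts are
merged before evaluation. Evaluating the error with the observed
proportions instead (a common shortcut) is overdispersed — a low-count
bin that fluctuates to zero annihilates its own variance term; with
the pooled form two independent simulations of the same model give
χ²ν ≈ 1, which is the property the test suite asserts. ν counts the
parameters actually varied. Mixture model histograms carry
pseudo-counts p·n_library; their true sampling variance is smaller by
f² + (1−f)², so mixture χ²ν is mildly conservative.

Parameter uncertainty comes from the χ²ν ≤ 1.5 region of the grid
(`confidenceRegion`), the convention used for the published error
bars.

**Lifetimes.** `fitLifetimes` holds D values, σ values and the ratio
τ_free/τ_bound = f_fast/f_slow fixed by the static fit, simulates
15,000-trajectory exchange ensembles over a log-spaced τ_free grid
(default 12 points, 0.1–100 ms), and minimizes χ²ν against the
experimental P(⟨r⟩₆) — one free parameter. All grid points share one
seed stream (common random numbers), which removes most of the
simulation noise from the objective's shape; a refinement pass at
double resolution around the coarse minimum is on by default. The
resolving power of this comparison is exactly why P(⟨r⟩₆) is used: a
static mixture at (0.3, 0.2/4.3 µm²/s) predicts two partially
resolved peaks, while exchange at τ_free = 16 ms averages each
trajectory over both states and produces a unimodal distribution.

## Synthetic data generator

`generateStudy` emits a full mock study: 120 cells with tip-to-tip
lengths drawn log-normally (median ≈ 4.3 µm, truncated to the observed
3.2–8.4 µm range, diameter 0.9 µm) and per-cell trajectory sets from a
named `studyPreset` carrying the condition's best-fit parameters
(wild-type EF-P with 16/7 ms exchange; ribosomes 0.2/0.8 µm²/s at
f_slow = 0.65; EF-P under chloramphenicol with 9/7 ms exchange, whose
lifetimes imply f_slow = 0.4375; EF-P under rifampin 4.6/8 µm²/s; the
non-binding K34A mutant 3.2/9.7 µm²/s). Trajectory lengths follow a
geometric law with mean 9 frames capped at 30 — a photobleaching
stand-in chosen so that 15 trajectories/cell leave ~860 six-step
trajectories after the ≥ 7-frame filter, the scale of the real
wild-type dataset; the corresponding pooled localization count then
exceeds the real study's, since one geometric law cannot match both.

For presets whose slow state is ribosome-bound, bound-state starting
positions are drawn from a three-zone axial weighting (Gaussian zones
at scaled −0.3, 0, +0.3, weights 0.4/0.2/0.4, sd 0.07·L) emulating the
nucleoid-excluded, ribosome-rich regions, so axial analyses have a
three-peak signal to detect; free molecules start uniformly. No
quantitative peak-to-trough contrast is claimed — the source material
gives none — so axial-contrast checks are qualitative (enrichment in
zones, trough below peaks). The generator does not emulate: blinking
or photophysics beyond length truncation, anomalous diffusion,
polysome size distributions, nucleoid polymer physics, bent or
dividing cells, or any spatial dependence of the *kinetics* (zones
affect initial positions only). Passing tests therefore validate the
inference machinery under the stated model, not those aspects of real
data.

## Imaging front end

`renderMovie` draws emitters as integrated-Gaussian PSFs accumulated
over the Brownian substeps within each exposure (motion blur), on a
uniform background with Poisson noise (EMCCD excess noise optionally
approximated by a factor-2 variance inflation). Pixel centres sit at
0-based integer indices × 160 nm; the renderer and `centroidLocalize`
share this convention. The analysis chain is deliberately simple and
configurable where the original description is not specific: 3×3
boxcar smoothing, frame-median background, strict 8-neighbour maxima
above a user-set threshold, 4 px peak merging keeping the brighter,
7×7 intensity-weighted centroid (robust to the asymmetric blur of a
moving emitter, unlike a Gaussian fit), and maximum-cardinality
minimum-cost frame-to-frame matching within a search radius — exact by
enumeration for sparse frames (0–2 molecules/frame), greedy beyond.
End-to-end validation renders bright single-state movies in a wide
(12 × 3 µm) domain — isolating the imaging chain from confinement
bias — and requires the MSD-recovered D within 15%.

## Census

`countProPro` counts overlapping Pro-Pro duets (PPPP → 3; a
non-overlapping flag exists). `motifFraction` is the copy-weighted
motif density Σ(motifs·copies)/Σ(length·copies). Note one arithmetic
wrinkle in the published chain: the printed totals 6.6×10⁵/1.3×10⁹
equal 5.08×10⁻⁴, while the chain continues with the printed rounded
value 5.3×10⁻⁴; `motifsPerCell(5.3e-4, 2000, 260)` reproduces the
published ≈ 280 motifs/cell. `interrogationBudget` chains the cycle
time τ_free + τ_bound = 23 ms into ~43.5 cycles/s per copy, 2.2–8.7 ×
10⁵ E-site interrogations/s for 5,000–20,000 copies, ~5–22 visits/s
per translating ribosome against 8×10⁵ elongation cycles/s, and
1,500–6,000 simultaneous complexes — all reported unrounded with
2-significant-figure companions. `syntheticProteome` builds a
determinstic random proteome whose copy-weighted motif fraction lands
within 10% of a target, by inserting spaced PP duets into
proline-free sequences with gene choice proportional to
length × copies.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use the study's own
scales: 5,200 single steps (867 six-step trajectories) for static
fits, 859 six-step trajectories for lifetime fits with 15,000 model
trajectories per τ point, 10,000-trajectory libraries (60,000 steps
per entry), 20-seed/10-seed replicate loops for the recovery checks,
and 10⁵-sample closed-form oracles. Degenerate inputs are handled
explicitly: empty histograms error, ν ≤ 0 errors, negative MSD
intercepts clamp with a flag, sub-six-step trajectories are skipped
with a warning, and grid minimizers on a boundary are flagged in the
fit object.

## Known limitations

- `D_slow` is weakly identified whenever its rms step is below the
  localization error (the reason the wild-type fit constrains it);
  unconstrained two-state fits on near-degenerate mixtures can wander
  a few grid steps at realistic sample sizes.
- The MSD-slope "mean D" of a two-state ensemble equals the
  occupancy-weighted average only without confinement; inside a
  0.9-µm cell the two-point slope reads low.
- Exchange lifetimes are only resolvable in the window set by the
  frame time and trajectory span (~1–50 ms here); outside it the χ²
  profile flattens toward the limits.
- The linker supports `memory = 0` only (a missed detection ends the
  trajectory), which matches the gap-splitting convention of the step
  statistics.
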