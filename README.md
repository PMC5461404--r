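# sptKinetics

Two-state binding kinetics from fast single-particle tracking in
bacteria.

## What this package is for

Fast sptPALM (2 ms/frame) can watch a single labelled protein — the
motivating case is the elongation factor EF-P — alternate between free
diffusion through the bacterial cytoplasm and transient binding to
translating ribosomes. Neither state is directly observable: every
displacement is distorted by 50–90 nm localization error, motion blur
during the exposure, and confinement inside the ~0.9 µm-wide
spherocylindrical cell. `sptKinetics` analyses such data the way the
field does when closed forms fail: it forward-simulates the entire
observation process and fits the data against simulated model
distributions.

The kinetic model is a two-state scheme: a molecule binds with rate
1/τ_free, unbinds with rate 1/τ_bound, and diffuses with D_slow while
bound and D_fast while free; the stationary bound fraction is
f_slow = τ_bound/(τ_bound + τ_free). The package fits

* static mixtures `P(r) = f_slow P(r; D_slow) + (1 − f_slow) P(r; D_fast)`
  to the single-step displacement histogram by reduced-χ² grid search
  over simulated model libraries, with χ²ν ≤ 1.5 confidence regions;
* exchange lifetimes to the six-step mean displacement histogram
  P(⟨r⟩₆), which distinguishes static mixtures (bimodal) from fast
  exchange (unimodal) on the 10 ms scale, with the lifetime ratio
  pinned by the static fractions.

Around this core it provides: a confined two-state Brownian simulator
(Rcpp) with per-trajectory reproducible streams; P(r), P(⟨r⟩₆), MSD
and per-trajectory diffusion statistics; axial distribution analysis
against the closed-form uniform spherocylinder null; a synthetic movie
renderer with centroid localization and Crocker–Grier-style linking;
full synthetic study bundles for five experimental conditions; and the
proteome Pro-Pro census and "E-site interrogation budget" arithmetic.

## Worked example

Simulate a wild-type-like dataset (859 six-step trajectories in a
4 × 0.9 µm cell), fit the static mixture with D_slow constrained to
the ribosome value, then fit the exchange lifetimes:

```r
library(sptKinetics)

cell <- Spherocylinder(4, 0.9)
cfg  <- SimConfig(nFrames = 7, cell = cell)
efp  <- TwoStateModel(Dslow = 0.2, Dfast = 4.3, tauFree = 16, tauBound = 7,
                      sigmaSlow = 50, sigmaFast = 75)

target <- simulateEnsemble(efp, cfg, nTraj = 859, seed = 7)
pr <- displacementPdf(singleStepDisplacements(target),
                      binWidth = 0.025, rMax = 1.2)

lib <- buildModelLibrary(defaultDGrid(), c(50, 75), cfg, nTraj = 10000,
                         seed = 99, binEdges = binEdges(pr))
fit <- fitStatic(pr, lib, nStates = 2, sigmaSlow = 50, sigmaFast = 75,
                 DslowFixed = 0.2)
fit$fit
#> StaticFit (2-state): chi2nu = 0.782
#>   D_slow = 0.195 (fixed), D_fast = 3.9, f_slow = 0.25
confidenceRegion(fit$grid, 1.5)$fSlow
#> min max
#> 0.2 0.3

r6  <- displacementPdf(meanSixStep(target), 0.025, 0.8,
                       kind = "six_step_mean")
kin <- fitLifetimes(r6, fit$fit, config = cfg, nTraj = 15000, seed = 7)
kin$fit
#> KineticFit: tau_free = 20.8 ms, tau_bound = 6.94 ms (ratio 3), chi2nu = 0.598
```

Reading the output: about a quarter to a third of the molecules are in
the slowly diffusing, ribosome-bound state at any instant
(f_slow grid value 0.25, χ²ν ≤ 1.5 region 0.2–0.3); the free-state
diffusion coefficient lands one grid step from the generating
4.3 µm²/s; and the lifetime fit recovers a free-state search time of
~21 ms and a ~7 ms bound-state residence time from a generating model
with τ_free = 16 ms, τ_bound = 7 ms — within the resolution this
sample size supports.

The census side needs no simulation:

```r
budget <- interrogationBudget(censusParams())
budget$cycleTime                 # 23 ms per search/bind cycle
#> [1] 23
round(budget$interrogationsPerS) # 217391 to 869565 E-site visits/s
#>    low   high
#> 217391 869565
budget$snapshotComplexes         # 1500 to 6000 simultaneous complexes
#>  low high
#> 1500 6000
```

Compare 280 Pro-Pro motifs per transcriptome
(`motifsPerCell(5.3e-4, 2000, 260)`) with 1,500–6,000 simultaneous
complexes: most binding events cannot be Pro-Pro rescues — the
quantitative core of the "housekeeping interrogation" interpretation.

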