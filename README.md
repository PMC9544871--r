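# f3flim

Photon-efficient lifetime extraction from time-domain FLIM (fluorescence
lifetime imaging) data by the centre-of-mass method (CMM) and its
three-window generalisation F3-CMM, together with a Monte-Carlo TCSPC
simulator, a least-squares baseline and the F / F′ photon-efficiency
figures of merit. It is aimed at FLIM users and method developers who want
fast, unbiased lifetime maps across a large lifetime dynamic range, and a
fully simulated test bed to quantify estimator performance.

## The method

For a decay histogram `I_k` on bins of width `Δ`, the centre-of-mass
lifetime is

```
τ_CM  = Σ I_k·kΔ / Σ I_k + Δ/2          (moment over the analysis window)
τ_CMM = τ_CM − τ_IRF                     (IRF first-moment subtraction)
τ_{k+1} = τ_CMM + Ta·e^(−Ta/τ_k) / (1 − e^(−Ta/τ_k))   (finite-window
          correction, Ta = window − τ_IRF, τ_0 = τ_CMM, 10 iterations)
```

preceded by subtraction of the pre-rise background level. Estimator
quality is measured by `F = √N·σ_τ/τ` (1 for an ideal, shot-noise-limited
estimator) and `F′ = √N·√(σ_τ²+Δτ²)/τ`, which also penalizes bias.

With background present, CMM loses efficiency for lifetimes short relative
to the analysis window. F3-CMM therefore runs CMM at three nested windows
(25 / 12.5 / 6.25 ns by default) and fuses the maps,

```
τ_F3 = W12·τ_T1 + (W23 − W12)·τ_T2 + (1 − W23)·τ_T3,
W_ij = 1 / (1 + e^(−b·(τ−τc_ij)/τc_ij)),   b = 20,
```

with weights evaluated at the middle-window pilot estimate. The cut-offs
`τc_ij = √(Ta_i·Ta_j·C/A)` come from a rational model of F′ versus
`α = τ/Ta`, `F′(α) = A·α + B + C/α`, fitted to a simulation study by
`calibrateF3()` (shipped defaults: A = 3.218, C = 0.07339).

## Worked example

```r
library(f3flim)

cfg <- simConfig(lifetimeMap = matrix(2.5, 16, 16),
                 photonMap   = matrix(5000, 16, 16),
                 afterpulsing = 0.05, seed = 42)
stk <- simulateStack(cfg)
map <- f3cmmStack(stk, gaussianIRF(3.2, 0.15))
summarizeLifetimeMap(map)
#>     n  mean      sd gaussMean gaussSd
#> 1 256 2.501 0.04196     2.501 0.04178

benchmarkEstimator("cmm", simConfig(afterpulsing = 0.05), tauGrid = 2.5,
                   nPhotons = 5000, nRepeats = 1024, seed = 42)
#>   tauTrue tauMean deltaTau sigmaTau fValue fPrime
#> 1     2.5   2.502 0.001552  0.04245  1.201  1.202
```

The 16×16 image simulated with a uniform 2.5 ns lifetime, 5000 photons per
pixel and 5% after-pulsing background is recovered without bias
(mean 2.501 ns) at ~42 ps precision; the benchmark row shows the same
estimator at F ≈ 1.2, i.e. within ~20% of the shot-noise limit despite the
background. A command-line front end for simulation, analysis,
calibration and benchmarking is installed at
`system.file("scripts", "f3flim.R", package = "f3flim")`:

```sh
Rscript f3flim.R simulate  --config sim.cfg --out stack.tif --seed 4
Rscript f3flim.R analyze   f3cmm --stack stack.tif --irf gauss:3.2,0.15 --out map.tif
Rscript f3flim.R benchmark --estimator cmm --tau-grid 0.5:4:0.5 --out bench.csv
```

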