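# Shared fixtures for the test suite. Everything is generated in code; the
# default acquisition geometry mirrors the bundled simulation studies
# (T = 25 ns, 256 bins, Gaussian IRF 3.2 +/- 0.15 ns).

defaultCfg <- function(ap = 0, seed = 1L, ...) {
  simConfig(afterpulsing = ap, seed = seed, ...)
}

defaultIRF <- function() gaussianIRF(3.2, 0.15)

# Noiseless binned exponential decay starting at t = 0: exact bin integrals
# of exp(-t/tau) on [0, nBins * dt).
noiselessDecay <- function(tau, dt = 25 / 256, nBins = 256) {
  edges <- (0:nBins) * dt
  tau * (exp(-edges[-(nBins + 1)] / tau) - exp(-edges[-1] / tau)) / tau
}

# Closed-form centre-of-mass of an exponential truncated to [0, Tw]:
# CM = tau - Tw * exp(-Tw/tau) / (1 - exp(-Tw/tau)).
closedFormCM <- function(tau, Tw) {
  tau - Tw * exp(-Tw / tau) / (1 - exp(-Tw / tau))
}

# Monte-Carlo standard error of a sample-sd-based F estimate.
fValueSE <- function(f, nRepeats) f / sqrt(2 * (nRepeats - 1))
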