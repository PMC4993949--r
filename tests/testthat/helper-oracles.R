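# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Closed-form first-passage time of a LIF neuron under constant current I
# (mV/ms): dV/dt = (vRest - V)/tauM + I from V = vRest crosses vThresh at
#   t* = tauM * log(Ieff / (Ieff - (vThresh - vRest))),  Ieff = I * tauM.
lifFirstPassage <- function(tauM, I, vRest = -70, vThresh = -54) {
  Ieff <- I * tauM
  gap <- vThresh - vRest
  if (Ieff <= gap) return(Inf)
  tauM * log(Ieff / (Ieff - gap))
}

# Homogeneous Poisson train by cumulative exponential waiting times —
# an implementation independent of rpois/runif-order used in the package.
cumExpPoisson <- function(rate, duration_ms) {
  if (rate <= 0) return(numeric())
  t <- 0
  out <- numeric()
  repeat {
    t <- t + stats::rexp(1, rate / 1000) # rate in Hz, time in ms
    if (t > duration_ms) break
    out <- c(out, t)
  }
  out
}

# Synthetic sinusoidal rate trace with white noise, as a RateTrace.
sineTrace <- function(freq, duration_ms = 4000, bin = 2, amp = 10,
                      base = 50, noise_sd = 0, freq2 = NULL, amp2 = 0) {
  t <- seq(0, duration_ms - bin, by = bin) / 1000
  x <- base + amp * sin(2 * pi * freq * t)
  if (!is.null(freq2)) x <- x + amp2 * sin(2 * pi * freq2 * t)
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
  new("RateTrace", population = "synthetic", binWidth = bin,
      rate = pmax(0, x))
}

# Minimal hand-built raster.
makeRaster <- function(events, duration, popSizes, seed = 0L) {
  o <- order(events$time)
  new("SpikeRaster", events = events[o, , drop = FALSE], duration = duration,
      popSizes = popSizes, seed = as.integer(seed))
}

# Single LIF neuron network under constant drive, used against the
# closed-form oracle.
singleNeuronNet <- function(tauM = 10, tRef = 2) {
  NetworkSpec(list(Population("n", 1L, "excitatory", tauM = tauM,
                              tRef = tRef)))
}

# A small config for fast experiment-level tests (not the shipped defaults).
tinyT2sConfig <- function(dir = tempdir()) {
  cfg <- defaultConfig("t2s")
  cfg$experiment$n_seeds <- 2L
  cfg$simulation$duration <- 2500
  cfg$drives$input1$offset <- 2500
  cfg$drives$input2$offset <- 2500
  cfg
}
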