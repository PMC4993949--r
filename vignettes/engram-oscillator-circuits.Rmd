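---
title: "Engram-oscillator circuits: converting between spatial and temporal neural codes"
author: "engramosc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engram-oscillator circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Memory engram cells are sparse neuronal ensembles whose reactivation
triggers recall. This package implements, as a reproducible spiking
simulator, a circuit hypothesis for how such spatially coded ensembles
could exchange information with temporally coded population oscillations:

* **Spatial to temporal (encoder).** Each engram source population reaches
  a downstream excitation–inhibition (E–I) oscillator through projections
  onto its excitatory cells and through two routes onto its inhibitory
  cells — a direct mono-synaptic projection and a di-synaptic route
  through a small excitatory relay. The mono/di weight ratio, at fixed
  total inhibitory-directed weight, determines the frequency and power of
  the oscillation the source evokes, so the *identity* of the active
  ensemble is re-expressed as an oscillation *frequency*.
* **Temporal to spatial (router).** An oscillatory drive (Input1,
  di-synaptic through a relay) and a constant drive (Input2,
  mono-synaptic) impinge on the oscillator's inhibitory population. The
  oscillator's excitatory spikes fan out to several small E–I engram
  readout parts with part-specific weights `wE` (onto the part's
  excitatory cells) and `wI` (onto its inhibitory cells). Each part
  responds selectively within its own drive-frequency band, so the
  oscillation frequency selects *which* ensemble ignites.

All neurons are current-based leaky integrate-and-fire (LIF) units,

$$\tau_m \frac{dV}{dt} = (V_\mathrm{rest} - V) + \tau_m I(t),$$

integrated by forward Euler at `dt = 0.1` ms, with threshold
$V_\mathrm{thresh}$, reset $V_\mathrm{reset}$, absolute refractoriness,
exponential synapses (an event of weight $w$ mV adds $w/\tau_s$ to an
input-current trace decaying with $\tau_s$, delivering $w$ millivolts of
charge in total), per-connection conduction delays, Bernoulli
connectivity masks, and independent per-neuron Poisson background spike
trains as the only noise source. Defaults: $\tau_m$ = 10 ms (excitatory)
/ 8 ms (inhibitory), rest and reset −70 mV, threshold −54 mV,
refractoriness 2 ms / 1 ms. Every simulation is reproducible bit-exactly
from its seed, which also fixes the connectivity masks.

These choices — the simplest spiking substrate that supports
pyramidal–interneuron (PING-type) population rhythms — are one admissible
realisation of the hypothesis, not a reproduction of any particular
published parameter set. The neuron equations, population sizes and noise
statistics are all configuration values, so alternatives can be swapped
in.

## How the router discriminates frequency

The two external inputs both target the inhibitory population, so driving
the circuit can only *redistribute* excitatory activity in time, never
raise its mean above the undriven baseline. The readout mechanism
therefore uses the temporal structure rather than the mean rate:

* Each half-rectified sine cycle of Input1 silences the oscillator's E
  population for roughly half a period (a *notch*), after which E firing
  resumes. Readout parts are tonically vetoed by their own inhibitory
  cells, which are driven from the same oscillator input (`wI`); after
  each notch both the excitation and the veto restart, and the part's E
  cells can fire only in the short race window before the veto
  re-engages. Responses therefore scale with the number of windows per
  second — but a window only opens if the veto's synaptic trace (4 ms
  decay) has decayed during the notch. Since notch duration is half the
  drive period, each part has a *high-frequency cutoff* set by `wI`.
* Parts with a high `wE`/`wI` ratio are tonically active at baseline.
  Their activation is measured as evoked rate minus baseline (floored at
  zero), so sparse low-frequency windows leave them *below* baseline:
  baseline flooring provides a *low-frequency cutoff*.

Combining the two cutoffs yields band-selective readout parts from
nothing but the two weights the hypothesis allows to differ:
`(wE, wI)` = (0.28, 0.19), (0.24, 0.15) and (0.20, 0.12) mV for the low
(20 Hz), medium (31 Hz) and high (44 Hz) bands. The bands are
octave-spaced (roughly theta–beta–low-gamma) because the cutoff contrast
grows exponentially with the notch-length difference; more closely spaced
bands degrade the winner margins quickly. Readout parts use 80 E / 20 I
neurons with dense input connectivity (p = 0.7): at 40 E / 10 I the
binomial variability of realised in-degrees dominated the winner margins.

## How the encoder maps ratio to frequency

The oscillation frequency of the balanced E–I circuit is controlled by
the net excitatory drive its E population receives (tonic drive onto I is
largely absorbed by the balance, shifting inhibitory rates rather than
the rhythm). The di-synaptic relay therefore carries a collateral onto
the E population in addition to its required projection onto I: at
di-dominant ratios the relay contributes strong E drive (fast rhythm,
~45 Hz at ratio 0.2), while at mono-dominant ratios the oscillator falls
back on its marginal direct drive (slow rhythm, ~21 Hz at ratio 12).
Between these extremes the seed-averaged map from ratio to peak frequency
is strictly monotone (the `sweep` experiment measures it: 51 → 21 Hz
over ratios 0.05–12), which is what makes spectrum-based decoding of
engram identity possible. The relay carries its own Poisson background;
without it the relay's regular firing entrains the oscillator at
subharmonics of the relay rate instead of moving smoothly with the
ratio.

Default encoder ratios are 12, 1.5 and 0.2, producing ≈21, ≈31 and
≈44 Hz — deliberately inside the router's three winner regions (≤22,
30–33 and 41–47 Hz at the default weight sets) so that the round-trip
composition is well defined.

## Quantification

* **Population rate**: spike count per bin divided by bin width and
  population size (Hz); summing `rate × bin × size` recovers the exact
  spike count.
* **Spectra**: Welch power spectral density of the z-scored rate trace
  (1 s Hann segments, 50% overlap, mean-detrended, band 2–80 Hz, DC
  excluded), giving ≤1 Hz resolution on the 3 s drive windows used by the
  experiments. z-scoring makes peak power comparable across conditions. A
  spectrum is flagged peakless when the trace is flat or the maximum does
  not exceed 8× the median in-band power — a white-noise spectrum stays
  well below this, any real oscillation far above; decoding refuses
  peakless spectra explicitly.
* **Activation delay**: start of the first run of `m` consecutive bins
  whose rate reaches `k`× the pre-onset baseline (absolute floor
  2 Hz, so silent baselines do not make stray spikes count). Function
  defaults are 10 ms bins, `k = 3`, `m = 3`; the shipped routing configs
  use 50 ms bins, `k = 2`, `m = 3` because band responses are
  burst-periodic (one burst per drive cycle, up to 50 ms apart at 20 Hz),
  so 10 ms bins can never be consecutively suprathreshold, and because
  the baseline-floored high-band part carries a tonic baseline that makes
  `k = 3` unattainable even during vigorous ignition.
* **Selectivity**: per condition and part, mean evoked rate in the drive
  window minus the pre-onset baseline, floored at zero and
  row-normalised; the row winner is the argmax, silent rows and ties are
  flagged.
* **Decoding**: nearest reference in (peak frequency, peak power) space,
  both coordinates standardised by the spread of the calibration
  references.

## Experiment drivers and problem sizes

Each driver derives per-trial seeds from the config's base seed by
counter, keeps every per-seed record in its report (all aggregates are
recomputable from them), and echoes the fully resolved config next to its
outputs. Defaults: 1 s silent baseline, 3 s drive window, 0.1 ms steps;
10 seeds per condition for routing (3 conditions), 20 seeds per engram
for encoding (first 10 calibrate the decoder, 10 are held out), 60
round-trip trials, 7-point ratio sweep at 5 seeds per point. These sizes
give ≤1 Hz spectral resolution and stable seed averages while keeping a
full experiment in the tens of seconds on one core.

```{r}
library(engramosc)
t2s <- runTemporalToSpatial(defaultConfig("t2s"))
show(t2s)
s2t <- runSpatialToTemporal(defaultConfig("s2t"))
rt  <- runRoundTrip(defaultConfig("roundtrip"))
tm  <- calibrateWeightFrequencyMap(defaultConfig("sweep"))
```

## What the simulations do and do not show

The generator's conditions are synthetic by construction: homogeneous
populations, Bernoulli connectivity, Poisson background, stationary
drives. Passing tests demonstrate that the two conversions are
*dynamically realisable* with biologically scaled parameters and that the
package's measurements behave correctly — they do not show that real
engram circuits use these mechanisms, nor do they survive heterogeneity,
plasticity, conduction-delay dispersion or non-stationary brain states,
none of which are modelled. Known limitations, made deliberately:

* No synaptic plasticity: consolidation is treated as a fixed-weight
  routing problem.
* No cross-inhibition between readout parts; winner margins rely purely
  on feedforward tuning. Cross-part inhibition would sharpen selectivity
  and is a natural extension.
* Current-based synapses and single-compartment neurons; no
  conductance effects, adaptation or rebound currents. The absence of
  slow intrinsic currents is why the encoder's range bottoms out near
  20 Hz rather than reaching theta proper.
* The router's oscillator follows Input1 faithfully only up to
  ≈45–48 Hz; beyond that it responds at subharmonics, which bounds the
  usable high band.

## Numerical and degenerate-input choices

Threshold crossings are detected at end-of-step; simultaneous spikes are
delivered in population-index order (this affects only bit-level
reproducibility, not dynamics). Synaptic delays must be at least one
integration step; network validation reports violations rather than
throwing. A drive window extending past the simulated duration is
truncated silently; a drive on an unknown population is a configuration
error raised before any stepping. Rates in empty populations are zero,
not errors; flat rate traces yield a flagged, peakless spectrum; decoding
a peakless spectrum returns an explicit no-oscillation result rather
than a guess. Non-finite membrane potentials (pathological weights)
abort the simulation with a diagnostic naming the neuron and time.
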