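# engramosc

Spiking-network simulation of engram–oscillator circuits: how a sparse,
*spatially* coded memory ensemble (an engram) can be converted into a
*temporally* coded population oscillation, and how oscillatory drive at
different frequencies can selectively reactivate distinct engram
populations.

The package is aimed at computational neuroscientists who want a small,
fully reproducible testbed for frequency-based routing between cell
assemblies: every network is built from explicit YAML/R configuration,
every simulation is bit-reproducible from its seed, and every experiment
ships with the analysis that quantifies it.

## The model

All neurons are current-based leaky integrate-and-fire units,

    tau_m dV/dt = (V_rest − V) + tau_m I(t),

(forward Euler, dt = 0.1 ms, threshold −54 mV, reset −70 mV, absolute
refractoriness, exponential synapses with per-connection delays,
Bernoulli connectivity, per-neuron Poisson background noise). Two circuit
motifs are built on top of a recurrently connected
excitation–inhibition (E–I) oscillator:

* **Encoder (spatial → temporal).** Engram source populations project to
  the oscillator's E cells and — via a mono-synaptic route and a
  di-synaptic route through an excitatory relay — to its I cells. The
  mono/di weight ratio at fixed total I-directed weight sets the
  frequency and power of the evoked oscillation, so each ensemble has its
  own spectral signature.
* **Router (temporal → spatial).** An oscillatory Input1 (di-synaptic)
  and a constant Input2 (mono-synaptic) drive the oscillator's I cells;
  the oscillator's E spikes fan out to three small E–I engram readout
  parts with part-specific weights (W_e, W_i). Each part ignites only in
  its own drive-frequency band (defaults: 20 / 31 / 44 Hz).

Quantification: binned population rates, Welch spectra of the z-scored
rate (1 s Hann segments, 50% overlap, 2–80 Hz), activation latency
(sustained rate-criterion runs), condition × part selectivity matrices,
and nearest-reference decoding of engram identity from (peak frequency,
peak power).

## Worked example

```r
library(engramosc)

t2s <- runTemporalToSpatial(defaultConfig("t2s"))
show(t2s)
#> ExperimentReport 'temporal_to_spatial': 10 seeds, config 2d593eef56d61dd174a34555b72a05b6
#>   flags: winners_correct=TRUE, margins_positive=TRUE, delay_within_200ms=TRUE

round(t2s@aggregate$activation, 3)
#>       [,1]  [,2]  [,3]
#> [1,] 0.391 0.351 0.258
#> [2,] 0.210 0.448 0.342
#> [3,] 0.169 0.360 0.471
t2s@aggregate$winners
#> [1] 1 2 3
round(t2s@aggregate$mean_delay, 1)
#> [1] 0 0 5
```

The seed-averaged selectivity matrix is row-normalised evoked activation
(drive conditions 20/31/44 Hz as rows, readout parts 1–3 as columns): its
diagonal dominance says each band ignites its own part, and the matched
parts reach sustained firing within 0–5 ms of drive onset on average —
far inside the ~200 ms the routing hypothesis calls "a very short
delay". The inverse conversion and the calibration sweep:

```r
s2t <- runSpatialToTemporal(defaultConfig("s2t"))
s2t@aggregate$mean_peak_frequency     # one oscillation frequency per engram
#> [1] 21.70 31.15 45.40
s2t@aggregate$decoding_accuracy       # identity decoded from spectra, held-out seeds
#> [1] 1

show(calibrateWeightFrequencyMap(defaultConfig("sweep")))
#> TransferMap: 7 control values, monotone regime [1..7]
#>   control peakFrequency peakPower
#> 1    0.05          51.4    0.1030
#> 2    0.15          45.6    0.0857
#> 3    0.40          40.2    0.1720
#> 4    1.00          33.2    0.2910
#> 5    2.20          26.6    0.3240
#> 6    5.00          22.0    0.3230
#> 7   12.00          21.0    0.2510
```

The transfer map is the package's central calibration: peak frequency is
strictly monotone in the mono/di ratio across the whole sampled range,
which is what makes the engram identity decodable from the oscillation
and the round-trip composition (`runRoundTrip()`) recover the activated
ensemble well above chance.

A thin command-line wrapper is provided for shell use:

```sh
exec/engramsim t2s --out-dir out/            # writes report.json + config.yaml
exec/engramsim sweep --config my_sweep.yaml --out-dir out/
exec/engramsim validate-config my_config.yaml
```

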