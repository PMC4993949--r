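# Spatial-to-temporal encoding: each engram source drives the oscillator
# with a distinct mono/di-synaptic weight ratio; ratio 12 / 1.5 / 0.2 give
# ~21 / ~31 / ~44 Hz oscillations (low / medium / high).
experiment:
  name: spatial_to_temporal
  n_seeds: 20
  n_calibration_seeds: 10
  base_seed: 42
network:
  oscillator:
    bgRateE: 1000.0
    bgWeightE: 1.0
    bgRateI: 200.0
    bgWeightI: 0.4
    wEE: 0.20
    pEE: 0.10
    wEI: 0.40
    pEI: 0.30
    wIE: 0.80
    pIE: 0.40
    wII: 0.20
    pII: 0.30
    tauSynE: 3.0
    tauSynI: 14.0
  ratios: [12.0, 1.5, 0.2]
drives:
  source: {amplitude: 3.0, onset: 1000.0, offset: 4000.0}
simulation:
  duration: 4000.0
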