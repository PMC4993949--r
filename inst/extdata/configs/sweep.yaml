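# Calibration sweep: mono/di ratio -> oscillation (frequency, power).
experiment:
  name: sweep
  n_seeds: 5
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
  ratios: [0.05, 0.15, 0.4, 1.0, 2.2, 5.0, 12.0]
drives:
  source: {amplitude: 3.0, onset: 1000.0, offset: 4000.0}
simulation:
  duration: 4000.0
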