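# Round trip: encode each engram as an oscillation (encoder section),
# replay its dominant frequency through the router, and require the
# matching readout part to win.
experiment:
  name: round_trip
  n_seeds: 20
  base_seed: 42
network:
  encoder_oscillator:
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
  oscillator:
    bgRateE: 2000.0
    bgWeightE: 1.0
    bgRateI: 500.0
    bgWeightI: 0.4
    wEE: 0.10
    pEE: 0.10
    wEI: 0.10
    pEI: 0.20
    wIE: 1.00
    pIE: 0.30
    wII: 0.30
    pII: 0.30
    tauSynE: 3.0
    tauSynI: 6.0
  weight_sets:
  - {index: 1, wE: 0.28, wI: 0.19}
  - {index: 2, wE: 0.24, wI: 0.15}
  - {index: 3, wE: 0.20, wI: 0.12}
  ratios: [12.0, 1.5, 0.2]
drives:
  input1: {amplitude: 4.0, onset: 1000.0, offset: 4000.0}
  input2: {amplitude: 0.5, onset: 0.0, offset: 4000.0}
  source: {amplitude: 3.0, onset: 1000.0, offset: 4000.0}
simulation:
  duration: 4000.0
analysis:
  delay: {bin: 50.0, k: 2.0, m: 3, floor_rate: 2.0}
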