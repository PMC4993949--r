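# Calibrated router readout weight sets: part k responds selectively to the
# k-th drive-frequency band (low 20 Hz / medium 31 Hz / high 44 Hz).
weight_sets:
- {index: 1, wE: 0.28, wI: 0.19}
- {index: 2, wE: 0.24, wI: 0.15}
- {index: 3, wE: 0.20, wI: 0.12}
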