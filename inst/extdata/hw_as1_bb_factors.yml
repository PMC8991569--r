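levels: coded
factors:
  - name: CaCl2
    unit: g/L
    low: 0.375
    center: 0.75
    high: 1.125
  - name: TraceElement
    unit: mL/L
    low: 0.25
    center: 0.5
    high: 0.75
  - name: Volume
    unit: mL/500 mL
    low: 75
    center: 150
    high: 225
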