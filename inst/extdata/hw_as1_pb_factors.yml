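levels: coded
factors:
  - name: Glucose
    unit: g/L
    low: 10
    high: 30
  - name: KNO3
    unit: g/L
    low: 7.5
    high: 22.5
  - name: K2HPO4
    unit: g/L
    low: 1.25
    high: 3.75
  - name: CaCl2
    unit: g/L
    low: 0.25
    high: 0.75
  - name: MgSO4
    unit: g/L
    low: 0.5
    high: 1.5
  - name: Tyrosine
    unit: g/L
    low: 0.5
    high: 1.5
  - name: TraceElement
    unit: mL/L
    low: 0.5
    high: 1.5
  - name: pH
    unit: pH units
    low: 4.5
    high: 6.5
  - name: CultureAge
    unit: days
    low: 4
    high: 10
  - name: InoculumSize
    unit: mL/L
    low: 0.5
    high: 1.5
  - name: Volume
    unit: mL/500 mL
    low: 50
    high: 150
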