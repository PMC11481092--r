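# Design-space presets: optimization variables with physical-unit bounds.
# Bounds are package defaults (documented assumptions consistent with the
# reactor model); override by editing a copy of this file.
step1:
  variables:
    - {name: T1, unit: degC, lower: 60, upper: 150, role: temperature}
    - {name: Q1, unit: mL/min, lower: 0.1, upper: 1.0, role: liquid_flow}
    - {name: C1, unit: mol/L, lower: 0.025, upper: 0.10, role: concentration}
step2:
  variables:
    - {name: T2, unit: degC, lower: 30, upper: 100, role: temperature}
    - {name: tau2, unit: min, lower: 0.5, upper: 5.0, role: residence_time}
    - {name: equiv3, unit: ratio, lower: 1.0, upper: 3.0, role: equivalents}
step2-im:
  variables:
    - {name: T2, unit: degC, lower: 30, upper: 100, role: temperature}
    - {name: tau2, unit: min, lower: 0.5, upper: 5.0, role: residence_time}
    - {name: equiv3, unit: ratio, lower: 1.0, upper: 3.0, role: equivalents}
telescoped:
  variables:
    - {name: T1, unit: degC, lower: 60, upper: 150, role: temperature}
    - {name: T2, unit: degC, lower: 30, upper: 100, role: temperature}
    - {name: Q1, unit: mL/min, lower: 0.1, upper: 1.0, role: liquid_flow}
    - {name: ratio, unit: ratio, lower: 2, upper: 10, role: flow_ratio}
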