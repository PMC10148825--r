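# Criteria for the bundled RTK-inhibitor case study: three angiogenic
# growth-factor criteria, all beneficial, threshold-free linear preference.
criteria:
  - name: GF1
    direction: beneficial
    weight: 0.45
    pf: {kind: paper-linear}
  - name: GF2
    direction: beneficial
    weight: 0.35
    pf: {kind: paper-linear}
  - name: GF3
    direction: beneficial
    weight: 0.20
    pf: {kind: paper-linear}
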