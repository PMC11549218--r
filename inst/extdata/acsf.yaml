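# Bicarbonate-buffered recording aCSF, speciated at pH 7.4:
# phosphate split across H2PO4-/HPO4 2- at pKa2 7.20 with the matching
# bicarbonate shift.
species:
  Na: 148.6
  K: 2.5
  Mg: 1.2
  Ca: 2.4
  Cl: 135.7
  HCO3: 20.6642
  H2PO4: 0.4642
  HPO4: 0.7358
temperature_K: 298.15
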