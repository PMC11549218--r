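# K-gluconate whole-cell pipette internal, speciated at pH 7.35:
# HEPES (pKa 7.55) enters as its anionic fraction; ATP/GTP as Mg
# complexes (effective valence -2); K is the KOH titration balance.
species:
  K: 148.8686
  Mg: 5.0
  Ca: 0.075
  Gluconate: 135.0
  Cl: 15.15
  HEPES: 3.8686
  EGTA: 0.1
  ATP: 2.0
  GTP: 0.4
temperature_K: 298.15
balance_ion: K
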