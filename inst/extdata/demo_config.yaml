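# Demo study: two substrains, three animals each, table-level composition,
# inheritance inference on the mononuclear-CM pattern, a small backcross
# simulation and the variant filter on a synthetic panel.
seed: 42
out_dir: ploidyscope_demo
population:
  strains: ["BALB/cJ", "BALB/cByJ"]
  n_animals: 3
  n_cells: 500
inference:
  parental_A: [low, low]        # [male, female] at strain A (BALB/cJ)
  parental_B: [high, high]      # strain B (BALB/cByJ)
  f1_mother_A: [low, low]       # F1 by maternal strain, [male, female]
  f1_mother_B: [high, low]
backcross:
  n_backcross: 3
  marker_pos_cm: 35
  n_replicates: 200
variants:
  n_strains: 8
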