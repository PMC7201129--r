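note: 'Versioned reference configuration: Table-of-constants defaults with the rate
  scale anchored so the baseline culture (full exchange every 48 h, growth factor
  1 ng/ml, 28 days) ends at 6.9e5 cells. Regenerate with perfusim::normalize_reference_configuration().'
anchor_cells: 690000.0
achieved_cells: 689999.900365409906954
kinetic_parameters:
  A1: 0.216
  A2: 5612000000000.0
  a1: 0.01
  a2: 0.03
  a3: 0.05
  Vo: 1.09e-17
  Vg: 9.5e-17
  Ko: 0.00182
  Kg: 0.3
  beta1: 255.0
  beta2: 360000.0
  gamma: 0.6716
  phi_cells: 25000000000000.0
  lam: 0.000128360588993
  alpha1: 0.975
  alpha2: 12.09
  alpha3: 0.1
  rate_scale: 6.835616533384387e-12
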