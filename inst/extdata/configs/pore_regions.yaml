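# Pore-region presets: two C-alpha rings delineating the central,
# roughly cylindrical section of the pore, in author residue numbering.
# Each C-alpha belongs to a different transmembrane helix. Radius in nm,
# chosen large enough to enclose all pore waters.
ucp2_nmr:
  bottom_resids: [34, 85, 137, 181, 239, 274]
  top_resids: [20, 101, 120, 194, 227, 288]
  r: 2
ucp2_h:
  bottom_resids: [34, 82, 137, 181, 274]
  top_resids: [20, 101, 120, 192, 288]
  r: 2
# Fitting protocol for the collective diffusion coefficient and the
# viscosity correction applied to P_f for TIP3P-like water models.
permeability_protocol:
  n_subtraj: 100
  subtraj_len_ps: 50
  viscosity_scale: 2.87
  vw_cm3: 2.99e-23
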