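# Concentrated BSA in 0.15 M NaCl at 25 degC, pH 4.5.
# Hydration from the homology-model SASA (GETAREA), monolayer coverage;
# ion binding from the Scatchard two-site model.
species:
  - id: water
    role: solvent
    molar_mass: 18.015
  - id: bsa
    role: protein
    molar_mass: 66430
  - id: nacl
    role: salt
    molar_mass: 58.443
    dissociation_count: 2
conditions:
  temperature_K: 298.15
binding:
  sasa_A2: 27746
  coverage_per_nm2: 15.2
  ion_binding_mol_per_mol: 11.59
prep:
  salt_M: 0.15
  basis_L: 1
  partial_specific_volume_mL_per_g: 0.733
  water_density_g_per_mL: 0.997
  conc_max_g_per_L: 475
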