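# Soil organic matter turnover network.  water_factor, MaxRootingDepth,
# annual C inputs, non-root input depth and the microbial C/N are the
# NCP-calibrated values; the pool rate coefficients, substrate-use
# efficiencies and partition fractions are literature-standard defaults for
# this pool family (slow/fast SOM and microbial biomass plus slow/fast added
# organic matter and an inert pool) and are all overridable.
pools: [SOM1, SOM2, SOM3, SMB1, SMB2, AOM1, AOM2]
# first-order decay coefficients, 1/h
pool_rate_coefficients:
  SOM1: 2.7e-6
  SOM2: 2.0e-5
  SOM3: 0.0
  SMB1: 1.85e-4
  SMB2: 1.0e-3
  AOM1: 5.0e-5
  AOM2: 2.0e-3
# flows: donor -> receiver with fraction of donor decay and substrate-use
# efficiency (1 - efficiency is respired as CO2)
flows:
- {donor: SOM1, receiver: SMB1, fraction: 1.00, efficiency: 0.40}
- {donor: SOM2, receiver: SMB1, fraction: 0.70, efficiency: 0.50}
- {donor: SOM2, receiver: SOM1, fraction: 0.30, efficiency: 0.40}
- {donor: SMB1, receiver: SOM2, fraction: 0.40, efficiency: 0.60}
- {donor: SMB1, receiver: SMB2, fraction: 0.60, efficiency: 0.60}
- {donor: SMB2, receiver: SOM2, fraction: 1.00, efficiency: 0.60}
- {donor: AOM1, receiver: SMB2, fraction: 1.00, efficiency: 0.60}
- {donor: AOM2, receiver: SMB2, fraction: 1.00, efficiency: 0.60}
smb_C_per_N: 4.8
smb_init_fraction: 0.02      # initial SMB C as fraction of total soil C
c_in_humus: 0.587            # g C per g organic matter
# denitrification water response: (relative saturation, factor) pairs
water_factor:
- [0.89, 0.01]
- [0.98, 0.01]
- [1.00, 0.01]
denit_potential_rate: 0.1    # 1/d on NO3-N at factor 1
nitrification_rate: 0.08     # 1/d on NH4-N at reference T and moisture
n2o_fraction_nitrification: 0.02
MaxRootingDepth: 190.0       # cm, end of root zone
annual_C_input:
  A: {total: 1550.0, root: 750.0}   # kg C/ha/y during warm-up
  B: {total: 800.0, root: 600.0}
nonroot_input_depth: 25.0    # cm
dispersivity: 5.0            # cm
nh4_kd: 0.4                  # linear sorption, cm3/g (retardation of NH4)
molecular_diffusion: 0.04    # cm2/h effective in solution
provenance:
  pool_rate_coefficients: default
  flows: default
  smb_C_per_N: literature
  smb_init_fraction: default
  c_in_humus: default
  water_factor: calibrated
  denit_potential_rate: default
  nitrification_rate: default
  n2o_fraction_nitrification: default
  MaxRootingDepth: measured
  annual_C_input: calibrated
  nonroot_input_depth: calibrated
  dispersivity: default
  nh4_kd: default
  molecular_diffusion: default
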