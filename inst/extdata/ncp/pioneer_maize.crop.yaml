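# Summer maize ("Pioneer maize" parameterisation, calibrated for the NCP).
# Fields tagged "default" in provenance are package defaults: values the
# published parameter table does not print (development rate after flowering,
# assimilate partitioning, temperature responses, organ N targets).
name: maize
EmrTSum: 200.0          # soil temperature sum to emergence, degC d
DSRate1: 0.0265         # vegetative development rate, 1/d
DSRate2: 0.020          # reproductive development rate, 1/d
Fm: 7.4                 # light-saturated leaf photosynthesis, g CO2/m2/h
QEff: 0.045             # quantum efficiency, (g CO2/m2/h)/(W/m2)
SpLAI: 0.02             # specific leaf area, (m2/m2)/(g DM/m2)
E_Leaf: 0.68
E_Stem: 0.60
E_SOrg: 0.75
r_Leaf: 0.015           # maintenance respiration, 1/d at 20 degC
r_Stem: 0.015
r_SOrg: 0.005
r_Root: 0.010
MaxPen: 150.0           # maximum root penetration, cm
MxNH4Up: 1.5e-7         # max NH4-N uptake, g N per cm root per h
MxNO3Up: 1.5e-7
SpRtLength: 130.0       # specific root length, m/g
root_penetration_rate: 2.5   # cm/d
C_per_N_slow_residue: 60.0   # C/N of slowly degradable leaf+stem residue
pet_factor_by_DS:
- [0.0, 1.0]
- [1.0, 1.3]
- [2.0, 1.2]
LeafAIMod_by_DS:
- [0.0, 0.7]
- [0.5, 0.8]
- [1.0, 1.2]
- [2.0, 0.2]
# fractions of net assimilate to [root, leaf, stem, storage organ]
partitioning_by_DS:
- [0.0, 0.40, 0.40, 0.20, 0.00]
- [0.5, 0.25, 0.45, 0.30, 0.00]
- [1.0, 0.10, 0.20, 0.50, 0.20]
- [1.3, 0.05, 0.05, 0.10, 0.80]
- [2.0, 0.00, 0.00, 0.00, 1.00]
# development-rate temperature modifier knots [T degC, factor]
temp_response_dev:
- [8.0, 0.0]
- [18.0, 1.0]
- [32.0, 1.0]
- [44.0, 0.0]
# photosynthesis temperature modifier
temp_response_phot:
- [6.0, 0.0]
- [16.0, 1.0]
- [36.0, 1.0]
- [46.0, 0.0]
# target (maximum) organ N concentration g N / g DM at DS knots
n_conc_by_DS:
  leaf:  [[0.0, 0.050], [1.0, 0.035], [2.0, 0.015]]
  stem:  [[0.0, 0.030], [1.0, 0.015], [2.0, 0.006]]
  sorg:  [[0.0, 0.016], [1.0, 0.016], [2.0, 0.014]]
  root:  [[0.0, 0.015], [1.0, 0.012], [2.0, 0.010]]
provenance:
  EmrTSum: calibrated
  DSRate1: calibrated
  DSRate2: default
  Fm: calibrated
  QEff: calibrated
  SpLAI: measured
  E_Leaf: calibrated
  E_Stem: calibrated
  E_SOrg: calibrated
  r_Leaf: calibrated
  r_Stem: calibrated
  r_SOrg: calibrated
  r_Root: default
  MaxPen: measured
  MxNH4Up: calibrated
  MxNO3Up: calibrated
  SpRtLength: measured
  root_penetration_rate: default
  C_per_N_slow_residue: calibrated
  pet_factor_by_DS: calibrated
  LeafAIMod_by_DS: calibrated
  partitioning_by_DS: default
  temp_response_dev: default
  temp_response_phot: default
  n_conc_by_DS: default
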