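# Winter wheat parameterisation, calibrated for the NCP.  Development stalls
# below the base temperature over winter (stands in for vernalisation).
name: wheat
EmrTSum: 100.0
DSRate1: 0.026
DSRate2: 0.028
Fm: 7.0
QEff: 0.052
SpLAI: 0.0201
E_Leaf: 0.78
E_Stem: 0.78
E_SOrg: 0.75
r_Leaf: 0.010
r_Stem: 0.010
r_SOrg: 0.005
r_Root: 0.008
MaxPen: 210.0
MxNH4Up: 2.5e-7
MxNO3Up: 2.5e-7
SpRtLength: 100.0
root_penetration_rate: 1.2
C_per_N_slow_residue: 100.0
pet_factor_by_DS:
- [0.0, 1.0]
- [1.0, 1.2]
- [2.0, 1.1]
LeafAIMod_by_DS:
- [0.0, 0.8]
- [0.5, 0.9]
- [1.0, 0.7]
- [2.0, 0.5]
partitioning_by_DS:
- [0.0, 0.45, 0.35, 0.20, 0.00]
- [0.5, 0.30, 0.40, 0.30, 0.00]
- [1.0, 0.10, 0.15, 0.45, 0.30]
- [1.3, 0.05, 0.05, 0.10, 0.80]
- [2.0, 0.00, 0.00, 0.00, 1.00]
temp_response_dev:
- [0.0, 0.0]
- [12.0, 1.0]
- [26.0, 1.0]
- [37.0, 0.0]
temp_response_phot:
- [0.0, 0.0]
- [10.0, 1.0]
- [28.0, 1.0]
- [40.0, 0.0]
n_conc_by_DS:
  leaf:  [[0.0, 0.055], [1.0, 0.040], [2.0, 0.018]]
  stem:  [[0.0, 0.035], [1.0, 0.018], [2.0, 0.007]]
  sorg:  [[0.0, 0.022], [1.0, 0.022], [2.0, 0.020]]
  root:  [[0.0, 0.015], [1.0, 0.012], [2.0, 0.010]]
provenance:
  EmrTSum: measured
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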