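# Default parameter file of the ctqsp platform.
#
# Every value here is configurable. Cellular-exposure and PBPK constants are
# placeholder, literature-sourced defaults -- they are NOT estimates from the
# calibration data and are not treated as ground truth anywhere in the test
# suite. Toxicodynamic (td) values are the interaction-fit preset.

td:
  k_inj: 0.0035        # 1/(h*umol/L) - injury rate per free intracellular doxorubicin
  tau: 4.9             # h - transit time per injured compartment
  EC50_kinMMP: 1.87    # umol/L - doxorubicin half-maximal effect on MMP production
  Emax_kinMMP: 1.0     # fixed
  k_in_MMP: 0.96       # 1/h (k_out_MMP tied equal: baseline MMP = 1)
  k_in_ATP: 0.032      # 1/h (k_out_ATP tied equal: baseline ATP = 1)
  "n": 0.8             # MMP -> ATP stimulation exponent (quoted: YAML 1.1 reads bare n as a boolean)
  Emax_kinATP: 0.54    # maximal fractional ATP-production inhibition by trastuzumab
  EC50_kinATP: 30.11   # nmol/L internalized trastuzumab
  k_TRZ_ATP50: 0.013   # 1/(nmol/L) - trastuzumab coefficient on ATP50
  k_e: 9.94            # 1/(h*umol/L) - doxorubicin enhancement rate
  MMP0: 1.0            # fixed baseline
  ATP50_ref: 0.5       # normalized ATP at half-maximal force (ACF_max = 1 + ATP50_ref)

dox_cellular:          # placeholder, literature-sourced, configurable
  V_cell: 4.0e-12      # L
  PER: 0.16            # cm/h
  S_cell: 1.5e-5       # cm^2
  k_pp: 1.3            # unbound in/ex partition ratio
  CN: 7.21e4           # umol/L DNA-binding domains
  k_d: 0.5             # umol/L drug-DNA dissociation constant

trz_cellular:          # placeholder, literature-sourced, configurable
  k_on: 2.56           # 1/((nmol/L)*h)
  k_off: 1.28          # 1/h  (Kd = 0.5 nmol/L)
  k_int: 0.12          # 1/h
  k_deg: 0.03          # 1/h
  k_dec: 0.001         # 1/h
  Ag_cell: 10          # nmol/L medium-referenced surface antigen

pbpk_dox:              # linear two-compartment surrogate
  CL: 55               # L/h
  V1: 25               # L
  V2: 1100             # L
  Q: 100               # L/h
  access: 0.006        # heart-interstitial effective access factor (calibrated)
  infusion_h: 1
  mw: 543.5            # g/mol

pbpk_trz:
  CL: 0.012            # L/h
  V1: 3.0              # L
  V2: 3.0              # L
  Q: 0.03              # L/h
  access: 0.20
  infusion_h: 1.5
  mw: 1.48e5
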