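# Default sediment-model parameters (Lake Baldegg configuration).
# Units as documented in ?default_parameters.
depth: 50
rho_b: 2.48
porosity: 0.84
sed_rate: 0.15
Db0: 1
H_bio: 0.5
tau_bio: 1.43
Db_min: 0.01
d_dbl: 0.082
k_deg_O2: 9.1
k_deg_NO3: 7.3
k_deg_MnO2: 1.08e-2
k_deg_FeOOH: 1.08e-2
k_deg_SO4: 1.44
k_deg_CH4: 5.28e-2
K_O2: 1.0e-3
K_NO3: 1.0e-3
K_MnO2: 16
K_FeOOH: 100
K_SO4: 0.1
k_nhox: 500
k_mox: 7500
k_fox: 1.0e+4
k_sox: 160
k_chox: 3.0e+5
k_nhmo: 7.5e-4
k_nhmx: 7.5e-5
k_nhfo: 9.45e-4
k_nhfx: 9.45e-5
k_fmo: 1.5e-2
k_fmx: 1.5e-3
k_smo: 1
k_smx: 0.1
k_sfo: 2.5
k_sfx: 0.25
k_chso: 0.5
k_moN: 1.0e+3
k_vivpre: 2.72e-5
k_vivdis: 1
k_EqViv: 3.0e-20
k_sviv: 10
k_FeSpre: 0.1
k_FeSdis: 2.0e-3
k_EqFeS: 6.3096
k_pyrpre: 4
k_MnCO3pre: 0.01064
k_EqHCO3CO3: 2.375e-5
k_EqMnCO3: 0.022
H_plus: 1.0e-7
L: 1.0e-8
f_dnra: 0.2
cx: 106
cy: 8
cz: 0.5
cs: 0.5
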