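# Default parameter profile: basal published rate constants plus the
# calibrated totals (BaxT, BclT), drug-term steepness (sigma_drug) and fate
# thresholds selected by calibrate_model(); see the methods vignette.
kf1: 1.0
kf2: 300.0
kb: 2.0
kasXC: 9000.0
kdsXC: 0.05
kasHC: 1000.0
kdsHC: 0.01
ksBh3: 0.1
ks2: 0.2
ks3: 1.0
kdBh3: 1.0
kaC8: 0.03
kiC8: 0.1
ki2: 0.15
ksIAP: 4.0e-05
ksIAP2: 0.016
kdIAP: 0.004
J: 0.1
"n": 10.0
R0_p53: -0.4
Rp53_p53: 2.0
RMdm2_p53: -1.0
R0_Mdm2: -0.55
Rp53_Mdm2: 1.0
sigma: 5.0
sigma2: 10.0
sigma_drug: 25.0
tsp53: 0.6
tsMdm2: 0.3
R_drug_effect: 0.33
BaxT: 0.5
BclT: 0.725
drug_coupling_mode: repressive
clamp_f: true
death_threshold: 0.1317253613
activation_threshold: 0.3
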