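outcome,group,diabetes,denervation,mean,sd,n
weight_initial,SHR,no,no,258,14,9
weight_initial,RD-SHR,no,yes,267,29,7
weight_initial,STZ-SHR,yes,no,269,13,9
weight_initial,RD-STZ-SHR,yes,yes,272,28,5
weight_45d,SHR,no,no,310,28,9
weight_45d,RD-SHR,no,yes,322,35,7
weight_45d,STZ-SHR,yes,no,275,53,9
weight_45d,RD-STZ-SHR,yes,yes,223,71,5
glycemia_initial,SHR,no,no,84.4,7,9
glycemia_initial,RD-SHR,no,yes,91.2,5,7
glycemia_initial,STZ-SHR,yes,no,414.1,135,9
glycemia_initial,RD-STZ-SHR,yes,yes,357.4,124,5
glycemia_45d,SHR,no,no,92.0,14,9
glycemia_45d,RD-SHR,no,yes,91.1,9,7
glycemia_45d,STZ-SHR,yes,no,417.5,114,9
glycemia_45d,RD-STZ-SHR,yes,yes,388.0,48,5
diuresis,SHR,no,no,11.2,4,9
diuresis,RD-SHR,no,yes,20.7,7,7
diuresis,STZ-SHR,yes,no,96.9,42,9
diuresis,RD-STZ-SHR,yes,yes,103.3,38,5
urinary_glucose,SHR,no,no,0.37,0.4,9
urinary_glucose,RD-SHR,no,yes,0.23,0.4,7
urinary_glucose,STZ-SHR,yes,no,758.0,544,9
urinary_glucose,RD-STZ-SHR,yes,yes,1019.0,379,5
urinary_sodium,SHR,no,no,1.03,0.3,9
urinary_sodium,RD-SHR,no,yes,1.29,0.8,7
urinary_sodium,STZ-SHR,yes,no,4.38,2.1,9
urinary_sodium,RD-STZ-SHR,yes,yes,4.50,1.8,5
densitometry,SHR,no,no,99.9,14,9
densitometry,RD-SHR,no,yes,185.6,13,7
densitometry,STZ-SHR,yes,no,182.7,21,9
densitometry,RD-STZ-SHR,yes,yes,201.4,25,5
hr_bpm,SHR,no,no,384.82,37.26,7
hr_bpm,RD-SHR,no,yes,431.32,36.60,6
hr_bpm,STZ-SHR,yes,no,316.21,5.17,6
hr_bpm,RD-STZ-SHR,yes,yes,363.81,12.25,5
sap_mmhg,SHR,no,no,178.43,16.07,7
sap_mmhg,RD-SHR,no,yes,171.03,5.22,6
sap_mmhg,STZ-SHR,yes,no,145.39,8.49,6
sap_mmhg,RD-STZ-SHR,yes,yes,157.20,26.41,5
dap_mmhg,SHR,no,no,141.17,19.10,7
dap_mmhg,RD-SHR,no,yes,150.27,13.52,6
dap_mmhg,STZ-SHR,yes,no,116.26,29.34,6
dap_mmhg,RD-STZ-SHR,yes,yes,118.88,10.75,5
map_mmhg,SHR,no,no,160.13,16.08,7
map_mmhg,RD-SHR,no,yes,165.25,8.89,6
map_mmhg,STZ-SHR,yes,no,129.22,5.66,6
map_mmhg,RD-STZ-SHR,yes,yes,139.90,9.15,5
hrv_total,SHR,no,no,69.84,37.91,7
hrv_total,RD-SHR,no,yes,55.75,25.21,6
hrv_total,STZ-SHR,yes,no,73.40,53.30,6
hrv_total,RD-STZ-SHR,yes,yes,148.39,93.58,5
hrv_lf_peak,SHR,no,no,0.64,0.06,7
hrv_lf_peak,RD-SHR,no,yes,0.69,0.08,6
hrv_lf_peak,STZ-SHR,yes,no,0.55,0.10,6
hrv_lf_peak,RD-STZ-SHR,yes,yes,0.54,0.14,5
hrv_lf,SHR,no,no,5.17,5.24,7
hrv_lf,RD-SHR,no,yes,1.62,0.98,6
hrv_lf,STZ-SHR,yes,no,2.12,0.97,6
hrv_lf,RD-STZ-SHR,yes,yes,7.38,6.52,5
hrv_lf_nu,SHR,no,no,26.84,19.05,7
hrv_lf_nu,RD-SHR,no,yes,26.07,13.63,6
hrv_lf_nu,STZ-SHR,yes,no,6.98,3.86,6
hrv_lf_nu,RD-STZ-SHR,yes,yes,16.58,7.99,5
hrv_hf_peak,SHR,no,no,2.42,0.58,7
hrv_hf_peak,RD-SHR,no,yes,2.12,0.82,6
hrv_hf_peak,STZ-SHR,yes,no,2.00,0.56,6
hrv_hf_peak,RD-STZ-SHR,yes,yes,2.31,0.65,5
hrv_hf,SHR,no,no,14.56,12.83,7
hrv_hf,RD-SHR,no,yes,4.14,3.09,6
hrv_hf,STZ-SHR,yes,no,32.11,15.88,6
hrv_hf,RD-STZ-SHR,yes,yes,37.22,20.54,5
hrv_hf_nu,SHR,no,no,73.16,19.05,7
hrv_hf_nu,RD-SHR,no,yes,72.90,12.59,6
hrv_hf_nu,STZ-SHR,yes,no,93.02,3.86,6
hrv_hf_nu,RD-STZ-SHR,yes,yes,83.42,7.99,5
lf_hf,SHR,no,no,0.47,0.47,7
lf_hf,RD-SHR,no,yes,0.49,0.32,6
lf_hf,STZ-SHR,yes,no,0.08,0.05,6
lf_hf,RD-STZ-SHR,yes,yes,0.21,0.11,5
sapv_total,SHR,no,no,68.33,36.16,7
sapv_total,RD-SHR,no,yes,61.89,24.84,6
sapv_total,STZ-SHR,yes,no,15.61,10.26,6
sapv_total,RD-STZ-SHR,yes,yes,29.86,20.69,5
sapv_vlf,SHR,no,no,77.13,54.27,7
sapv_vlf,RD-SHR,no,yes,38.00,27.50,6
sapv_vlf,STZ-SHR,yes,no,12.91,8.11,6
sapv_vlf,RD-STZ-SHR,yes,yes,46.20,47.03,5
sapv_lf_peak,SHR,no,no,0.44,0.06,7
sapv_lf_peak,RD-SHR,no,yes,0.53,0.06,6
sapv_lf_peak,STZ-SHR,yes,no,0.36,0.07,6
sapv_lf_peak,RD-STZ-SHR,yes,yes,0.40,0.08,5
sapv_lf,SHR,no,no,18.49,18.17,7
sapv_lf,RD-SHR,no,yes,3.69,3.10,6
sapv_lf,STZ-SHR,yes,no,1.38,1.38,6
sapv_lf,RD-STZ-SHR,yes,yes,56.61,26.75,5
sapv_hf_peak,SHR,no,no,1.72,0.68,7
sapv_hf_peak,RD-SHR,no,yes,2.12,0.56,6
sapv_hf_peak,STZ-SHR,yes,no,1.19,0.22,6
sapv_hf_peak,RD-STZ-SHR,yes,yes,1.52,0.48,5
sapv_hf,SHR,no,no,4.67,5.09,7
sapv_hf,RD-SHR,no,yes,53.94,17.65,6
sapv_hf,STZ-SHR,yes,no,5.66,5.45,6
sapv_hf,RD-STZ-SHR,yes,yes,6.27,10.70,5
alpha_lf,SHR,no,no,0.54,0.16,7
alpha_lf,RD-SHR,no,yes,0.86,0.56,6
alpha_lf,STZ-SHR,yes,no,1.44,0.38,6
alpha_lf,RD-STZ-SHR,yes,yes,1.73,1.38,5
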