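variable,group,mean,sd,n
age,none,37.08,11.07,23
age,acute,36.88,9.45,12
age,chronic,34.43,9.51,18
years_post_injury,acute,0.23,0.05,12
years_post_injury,chronic,10.08,7.19,18
age_at_injury,acute,36.67,9.46,12
age_at_injury,chronic,24.36,7.77,18
mir148a_3p,none,9731.65,4406.23,23
mir148a_3p,acute,13241.08,2927.81,12
mir148a_3p,chronic,9407.89,2463.35,18
mir148a_5p,none,88.30,48.13,23
mir148a_5p,acute,130.16,64.73,12
mir148a_5p,chronic,92.11,27.17,18
bmi,none,24.22,3.21,21
bmi,acute,23.51,4.30,12
bmi,chronic,23.28,4.66,18
mat_diaphysis_cm3,acute,3.45,1.77,12
mat_diaphysis_cm3,chronic,7.80,4.08,18
bmc_diaphysis_g,acute,1.19,0.92,12
bmc_diaphysis_g,chronic,-0.52,0.63,18
bmc_epiphysis_g,acute,10.79,3.48,12
bmc_epiphysis_g,chronic,3.22,2.10,18
bmc_metaphysis_g,acute,3.24,1.79,12
bmc_metaphysis_g,chronic,-0.24,1.26,18
bmc_total_g,acute,15.22,5.95,12
bmc_total_g,chronic,2.44,3.47,18
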