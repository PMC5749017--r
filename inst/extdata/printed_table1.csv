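characteristic,kind,a_mean,a_sd,a_p,b_mean,b_sd,b_p,std_diff
maternal_age,continuous,29.9,5.5,NA,30.2,5.3,NA,-0.1
rural,binary,NA,NA,0.105,NA,NA,0.244,-0.4
region_canada,binary,NA,NA,0.749,NA,NA,0.876,-0.3
region_europe_western,binary,NA,NA,0.040,NA,NA,0.041,0.0
region_africa_caribbean,binary,NA,NA,0.032,NA,NA,0.015,0.1
region_middle_east_n_africa,binary,NA,NA,0.026,NA,NA,0.014,0.1
region_latin_america,binary,NA,NA,0.019,NA,NA,0.014,0.0
region_south_asia,binary,NA,NA,0.079,NA,NA,0.015,0.3
region_east_asia,binary,NA,NA,0.057,NA,NA,0.026,0.2
income_q1,binary,NA,NA,0.220,NA,NA,0.175,0.1
income_q2,binary,NA,NA,0.200,NA,NA,0.188,0.0
income_q3,binary,NA,NA,0.203,NA,NA,0.218,0.0
income_q4,binary,NA,NA,0.207,NA,NA,0.216,0.0
income_q5,binary,NA,NA,0.165,NA,NA,0.199,-0.1
income_unknown,binary,NA,NA,0.005,NA,NA,0.004,0.0
birthweight,continuous,3461,472,NA,3490,464,NA,-0.1
gestational_age,continuous,39.2,1.1,NA,39.3,1.1,NA,-0.1
male_sex,binary,NA,NA,0.507,NA,NA,0.514,0.0
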