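covariate,level,age_days,n,rate,rr,ci_low,ci_high,is_referent
overall,Overall,60,7621,39.5,NA,NA,NA,FALSE
overall,Overall,122,7416,32.4,NA,NA,NA,FALSE
overall,Overall,182,7186,25.1,NA,NA,NA,FALSE
maternal_age_band,<20,60,207,20.8,1.00,NA,NA,TRUE
maternal_age_band,20-24,60,979,28.7,1.38,1.04,1.84,FALSE
maternal_age_band,25-29,60,2114,37.4,1.80,1.37,2.36,FALSE
maternal_age_band,30-34,60,2691,43.7,2.10,1.61,2.75,FALSE
maternal_age_band,35-39,60,1362,44.6,2.15,1.63,2.82,FALSE
maternal_age_band,>=40,60,268,41.8,2.01,1.49,2.72,FALSE
maternal_age_band,<20,122,201,15.4,1.00,NA,NA,TRUE
maternal_age_band,20-24,122,950,20.8,1.35,0.96,1.91,FALSE
maternal_age_band,25-29,122,2054,29.9,1.94,1.39,2.70,FALSE
maternal_age_band,30-34,122,2637,36.6,2.37,1.71,3.29,FALSE
maternal_age_band,35-39,122,1315,37.6,2.44,1.75,3.39,FALSE
maternal_age_band,>=40,122,259,38.6,2.50,1.75,3.58,FALSE
maternal_age_band,<20,182,195,12.8,1.00,NA,NA,TRUE
maternal_age_band,20-24,182,924,16.2,1.27,0.85,1.88,FALSE
maternal_age_band,25-29,182,1983,22.3,1.74,1.20,2.54,FALSE
maternal_age_band,30-34,182,2557,28.5,2.23,1.54,3.23,FALSE
maternal_age_band,35-39,182,1275,29.3,2.29,1.57,3.33,FALSE
maternal_age_band,>=40,182,252,31.3,2.45,1.62,3.68,FALSE
parity_band,Multiparous,60,4029,39.3,1.00,NA,NA,TRUE
parity_band,Primiparous,60,3592,39.6,1.01,0.95,1.07,FALSE
parity_band,Multiparous,122,3912,31.9,1.00,NA,NA,TRUE
parity_band,Primiparous,122,3504,32.9,1.03,0.97,1.10,FALSE
parity_band,Multiparous,182,3791,24.5,1.00,NA,NA,TRUE
parity_band,Primiparous,182,3395,25.7,1.05,0.97,1.14,FALSE
urban,no,60,1828,33.3,1.00,NA,NA,TRUE
urban,yes,60,5790,41.4,1.24,1.16,1.34,FALSE
urban,no,122,1780,26.7,1.00,NA,NA,TRUE
urban,yes,122,5633,34.2,1.28,1.17,1.39,FALSE
urban,no,182,1719,19.8,1.00,NA,NA,TRUE
urban,yes,182,5464,26.7,1.35,1.22,1.50,FALSE
immigrant,no,60,6694,39.2,1.00,NA,NA,TRUE
immigrant,yes,60,927,41.4,1.06,0.97,1.15,FALSE
immigrant,no,122,6514,32.1,1.00,NA,NA,TRUE
immigrant,yes,122,902,34.6,1.08,0.98,1.19,FALSE
immigrant,no,182,6309,24.7,1.00,NA,NA,TRUE
immigrant,yes,182,877,27.4,1.11,0.98,1.24,FALSE
income_quintile,Q1,60,1314,35.9,1.00,NA,NA,TRUE
income_quintile,Q2,60,1430,39.0,1.08,0.98,1.19,FALSE
income_quintile,Q3,60,1706,39.5,1.10,1.00,1.21,FALSE
income_quintile,Q4,60,1646,42.6,1.19,1.08,1.30,FALSE
income_quintile,Q5,60,1497,39.9,1.11,1.01,1.22,FALSE
income_quintile,unknown,60,28,21.4,0.60,0.29,1.22,FALSE
income_quintile,Q1,122,1268,28.2,1.00,NA,NA,TRUE
income_quintile,Q2,122,1386,32.5,1.15,1.03,1.30,FALSE
income_quintile,Q3,122,1667,32.9,1.17,1.04,1.31,FALSE
income_quintile,Q4,122,1608,35.9,1.27,1.14,1.42,FALSE
income_quintile,Q5,122,1461,31.8,1.13,1.01,1.27,FALSE
income_quintile,unknown,122,26,15.4,0.55,0.22,1.35,FALSE
income_quintile,Q1,182,1229,20.5,1.00,NA,NA,TRUE
income_quintile,Q2,182,1342,26.5,1.29,1.12,1.49,FALSE
income_quintile,Q3,182,1617,26.1,1.27,1.11,1.46,FALSE
income_quintile,Q4,182,1556,27.5,1.34,1.17,1.54,FALSE
income_quintile,Q5,182,1417,24.1,1.18,1.02,1.36,FALSE
income_quintile,unknown,182,25,8.0,0.39,0.10,1.48,FALSE
income_immigrant,Q1 & non-immigrant,60,1063,34.2,1.00,NA,NA,TRUE
income_immigrant,Q1 & immigrant,60,251,43.0,1.26,1.07,1.48,FALSE
income_immigrant,Q2-Q5 & non-immigrant,60,5613,40.2,1.17,1.07,1.28,FALSE
income_immigrant,Q2-Q5 & immigrant,60,666,41.0,1.20,1.06,1.35,FALSE
income_immigrant,unknown,60,28,21.4,0.63,0.31,1.28,FALSE
income_immigrant,Q1 & non-immigrant,122,1019,26.4,1.00,NA,NA,TRUE
income_immigrant,Q1 & immigrant,122,249,35.3,1.34,1.10,1.63,FALSE
income_immigrant,Q2-Q5 & non-immigrant,122,5478,33.2,1.26,1.13,1.40,FALSE
income_immigrant,Q2-Q5 & immigrant,122,644,34.6,1.31,1.13,1.52,FALSE
income_immigrant,unknown,122,26,15.4,0.58,0.24,1.44,FALSE
income_immigrant,Q1 & non-immigrant,182,985,18.9,1.00,NA,NA,TRUE
income_immigrant,Q1 & immigrant,182,244,27.0,1.43,1.12,1.83,FALSE
income_immigrant,Q2-Q5 & non-immigrant,182,5307,25.9,1.37,1.20,1.57,FALSE
income_immigrant,Q2-Q5 & immigrant,182,625,27.7,1.47,1.22,1.76,FALSE
income_immigrant,unknown,182,25,8.0,0.42,0.11,1.61,FALSE
birthweight_band,<2500,60,92,34.8,1.00,NA,NA,TRUE
birthweight_band,2500-<3000,60,895,39.7,1.14,0.85,1.53,FALSE
birthweight_band,3000-<3500,60,2872,39.0,1.12,0.85,1.49,FALSE
birthweight_band,>=3500,60,3762,39.9,1.15,0.86,1.52,FALSE
birthweight_band,<2500,122,89,22.5,1.00,NA,NA,TRUE
birthweight_band,2500-<3000,122,858,33.1,1.47,0.99,2.19,FALSE
birthweight_band,3000-<3500,122,2795,32.5,1.45,0.98,2.13,FALSE
birthweight_band,>=3500,122,3674,32.4,1.44,0.98,2.12,FALSE
birthweight_band,<2500,182,83,19.3,1.00,NA,NA,TRUE
birthweight_band,2500-<3000,182,830,27.1,1.41,0.89,2.21,FALSE
birthweight_band,3000-<3500,182,2702,25.1,1.30,0.84,2.03,FALSE
birthweight_band,>=3500,182,3571,24.7,1.28,0.82,2.00,FALSE
birth_year_band,2002-2007,60,1739,32.7,1.00,NA,NA,TRUE
birth_year_band,2008-2013,60,5882,41.5,1.27,1.18,1.36,FALSE
birth_year_band,2002-2007,122,1724,26.3,1.00,NA,NA,TRUE
birth_year_band,2008-2013,122,5692,34.2,1.30,1.19,1.42,FALSE
birth_year_band,2002-2007,182,1709,20.4,1.00,NA,NA,TRUE
birth_year_band,2008-2013,182,5477,26.5,1.30,1.17,1.45,FALSE
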