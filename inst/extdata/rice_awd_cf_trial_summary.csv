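population,n_genotypes,trait,system,mean,sd,fixed_var,sigma2_g,sigma2_gy,sigma2_e,total,r2_cond,h2,rG,rG_lower,rG_upper,cr_dr
reference,284,FL,AWD,100.3,7.8,44.12,57.68,10.90,11.28,123.98,0.91,0.89,0.955,0.943,0.964,0.98
reference,284,FL,CF,93.4,7.0,8.43,47.78,4.36,5.95,66.52,0.91,0.94,NA,NA,NA,NA
reference,284,NI,AWD,20.1,2.0,0.91,4.99,1.22,14.71,21.83,0.33,0.61,0.589,0.508,0.661,0.56
reference,284,NI,CF,23.7,2.5,1.50,6.17,4.09,16.75,28.50,0.41,0.56,NA,NA,NA,NA
reference,284,PW,AWD,252.9,57.9,720.96,3435.39,949.48,3142.66,8248.49,0.62,0.76,0.773,0.722,0.816,0.82
reference,284,PW,CF,342.3,71.1,119.98,5088.95,850.38,2437.24,8496.55,0.71,0.85,NA,NA,NA,NA
progeny,97,FL,AWD,102.8,6.1,40.94,35.15,8.17,11.78,96.04,0.88,0.85,0.897,0.850,0.930,0.90
progeny,97,FL,CF,92.9,5.2,27.97,23.20,7.38,2.27,60.81,0.96,0.85,NA,NA,NA,NA
progeny,97,NI,AWD,17.1,1.5,1.55,3.03,0.00,5.32,9.90,0.46,0.76,0.731,0.622,0.812,0.75
progeny,97,NI,CF,18.4,2.0,2.63,4.12,0.70,3.72,11.16,0.67,0.80,NA,NA,NA,NA
progeny,97,PW,AWD,199.9,51.3,889.23,2487.80,466.32,522.24,4365.59,0.88,0.88,0.848,0.781,0.896,0.86
progeny,97,PW,CF,277.6,53.0,258.26,2698.52,415.49,554.00,3926.27,0.86,0.90,NA,NA,NA,NA
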