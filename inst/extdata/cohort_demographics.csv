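variable,test,mean1,sd1,n1,mean2,sd2,n2,a,b,c,d
Age,pooled_t,36.75,13.62,63,34.53,13.13,55,NA,NA,NA,NA
Sex,chi2,NA,NA,NA,NA,NA,NA,42,21,38,17
Smoker,chi2,NA,NA,NA,NA,NA,NA,18,42,17,38
BPRS_Total,welch_t,24.1,4.91,63,37.09,12.39,55,NA,NA,NA,NA
APTS_State,welch_t,0.08,0.22,63,0.72,0.94,55,NA,NA,NA,NA
APTS_Trait,welch_t,0.42,0.48,63,1.44,1.23,55,NA,NA,NA,NA
VPTS_State,welch_t,1.28,3.19,63,14.93,20.89,55,NA,NA,NA,NA
VPTS_Trait,welch_t,0.19,0.24,63,1,1.09,55,NA,NA,NA,NA
Working_Memory,welch_t,21.43,4.06,63,18.55,5.21,55,NA,NA,NA,NA
Processing_Speed,welch_t,76.54,14.07,63,62.37,20.51,55,NA,NA,NA,NA
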