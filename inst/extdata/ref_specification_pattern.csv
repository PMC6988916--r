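sample,level,n,lhr_sem,sig_sem,lhr_slx,sig_slx,lhr_ols,sig_ols,selected
PAN,macro,49,0.56,FALSE,10.21,TRUE,12.71,TRUE,SEM
PAN,meso,361,3.02,FALSE,172.50,TRUE,188.98,TRUE,SEM
PAN,micro,3035,133.63,TRUE,1804.10,TRUE,2000.90,TRUE,SDEM
ZAM,macro,9,1.70,FALSE,0.08,FALSE,2.78,FALSE,OLS
ZAM,meso,70,0.12,FALSE,7.36,TRUE,7.90,TRUE,SEM
ZAM,micro,1016,37.59,TRUE,686.60,TRUE,808.74,TRUE,SDEM
ECU,macro,24,5.41,FALSE,0.22,FALSE,6.04,FALSE,OLS
ECU,meso,212,10.82,TRUE,36.63,TRUE,48.89,TRUE,SDEM
ECU,micro,865,36.31,TRUE,199.33,TRUE,226.20,TRUE,SDEM
PHI,macro,16,1.59,FALSE,0.73,FALSE,2.69,FALSE,OLS
PHI,meso,79,12.73,TRUE,0.77,FALSE,15.52,TRUE,SLX
PHI,micro,1154,14.43,TRUE,265.63,TRUE,281.91,TRUE,SDEM
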