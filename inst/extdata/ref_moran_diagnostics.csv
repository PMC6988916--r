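sample,level,n,I,expectation,variance,sd
PAN,macro,49,0.41,-3.95e-2,1.04e-2,4.40
PAN,meso,361,0.52,-8.96e-3,1.31e-3,14.74
PAN,micro,3035,0.58,-1.12e-3,1.71e-4,44.55
ZAM,macro,9,-0.18,-1.66e-1,3.84e-2,-0.09
ZAM,meso,70,0.23,-3.06e-2,6.05e-3,3.41
ZAM,micro,1016,0.58,-3.11e-3,4.63e-4,27.09
ECU,macro,24,0.13,-8.47e-2,1.71e-2,1.64
ECU,meso,212,0.29,-1.47e-2,2.17e-3,6.58
ECU,micro,865,0.35,-3.97e-3,5.28e-4,15.49
PHI,macro,16,-0.15,-7.53e-2,2.69e-2,-0.48
PHI,meso,79,0.10,-2.27e-2,5.88e-3,1.59
PHI,micro,1154,0.40,-2.82e-3,5.21e-4,17.48
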