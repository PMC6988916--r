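variable,direct,indirect,total
PVA,-0.09,-0.04,-0.13
PP_FA,1.21,-0.09,1.11
RD,0.01,-0.12,-0.11
CSI,0.15,0.22,0.37
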