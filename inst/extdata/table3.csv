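response,rep1,rep2,rep3,printed_mean,printed_s_pred,printed_rsd_pct
size_nm,180.1,175.0,180.6,178.6,9.52,5.35
pdi,0.250,0.230,0.252,0.244,0.009,3.69
zeta_mv,-12.6,-11.4,-12.5,-12.2,1.57,12.9
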