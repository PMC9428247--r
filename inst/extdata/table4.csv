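sample,tm_c,dh_j_g,ci_pct
Phenobarbital,175.4,127.1,100
Myristyl myristate,31.1-42.8,241.6,100
Poloxamer 188,54.2,156.6,100
NLC-vehicle,41.3-51.7,91.6,12.6
NLC-PB,41.4-49.7,96.7,13.3
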