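sample,two_theta_deg,theta_deg,d_spacing_a
Myristyl myristate,21.67,10.8,0.41
Myristyl myristate,23.87,11.9,0.37
Poloxamer 188,19.13,9.56,0.46
Poloxamer 188,23.29,11.6,0.38
Phenobarbital,15.17,7.58,0.58
Phenobarbital,16.50,8.25,0.54
Phenobarbital,21.96,11.0,0.40
NLC-vehicle,19.13,9.56,0.46
NLC-vehicle,21.64,10.8,0.41
NLC-vehicle,23.33,11.7,0.38
NLC-vehicle,23.90,11.9,0.37
NLC-PB,19.18,9.59,0.46
NLC-PB,21.64,10.8,0.41
NLC-PB,23.33,11.7,0.38
NLC-PB,23.90,11.9,0.37
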