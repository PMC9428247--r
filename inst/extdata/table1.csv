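run,lipid_mg,surfactant_mg,oil_ul,sonication_min,power_pct,size_nm,pdi,zeta_mv
1,100,400,10,10,60,150.2,0.236,-9.56
2,100,400,10,40,60,144.0,0.233,-8.53
3,100,400,200,10,80,198.5,0.189,-11.4
4,100,400,200,40,80,201.2,0.118,-5.72
5,100,800,10,10,80,189.1,0.234,-4.42
6,100,800,10,40,80,188.5,0.212,-1.15
7,100,800,200,10,60,199.5,0.148,-5.45
8,100,800,200,40,60,174.2,0.165,-4.86
9,400,400,10,10,80,240.1,0.184,-14.1
10,400,400,10,40,80,242.6,0.114,-14.5
11,400,400,200,10,60,216.2,0.064,-18.1
12,400,400,200,40,60,245.8,0.158,-16.8
13,400,800,10,10,60,215.7,0.207,-11.2
14,400,800,10,40,60,208.6,0.200,-7.08
15,400,800,200,10,80,210.7,0.174,-4.49
16,400,800,200,40,80,191.4,0.208,-1.49
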