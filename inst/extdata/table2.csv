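run,lipid_mg,surfactant_mg,size_nm,pdi,zeta_mv
1,500.0,700.0,144.2,0.254,-10.3
2,500.0,700.0,145.6,0.248,-8.31
3,500.0,700.0,146.0,0.260,-8.95
4,250.0,900.0,183.3,0.376,-2.14
5,500.0,700.0,153.9,0.256,-9.35
6,750.0,500.0,199.2,0.240,-8.53
7,250.0,500.0,170.8,0.370,-1.10
8,853.6,700.0,164.1,0.263,-9.22
9,500.0,417.2,164.5,0.305,-11.2
10,750.0,900.0,169.7,0.238,-4.76
11,500.0,700.0,153.3,0.280,-5.12
12,500.0,982.8,155.4,0.282,-7.43
13,146.4,700.0,219.2,0.433,-2.74
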