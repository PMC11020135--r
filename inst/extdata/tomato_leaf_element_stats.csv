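element,min_ppm,mean_ppm,max_ppm,sd_ppm,cv_percent
Li,1.15,5.17,15.4,2.79,54
B,4.01,24.8,70.8,11.9,48
Na,121,481,1510,275,57
Mg,2320,5560,12200,2090,38
P,2610,5910,12800,2010,34
S,2350,6530,16300,2600,40
K,2680,9820,23700,4110,42
Ca,6060,19600,50900,8000,41
Mn,18.3,49.9,126.3,21.2,42
Fe,43.3,97.8,239,37.9,39
Co,0.054,0.20,0.57,0.10,54
Cu,5.40,11.9,29.0,4.36,37
Zn,4.70,17.8,51.4,8.96,50
Rb,3.25,27.7,92.7,18.0,65
Sr,11.8,46.6,141,23.0,49
Mo,0.40,1.19,2.77,0.48,41
Cd,0.003,0.03,0.09,0.02,64
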