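species,or_lower_mean,or_lower_sd,rfi_upper_mean,rfi_upper_sd,rfi_lower_mean,rfi_lower_sd,sq_upper_mean,sq_upper_sd,sq_lower_mean,sq_lower_sd
Alouatta palliata,1.72,0.06,0.46,0.07,0.5,0.02,35.72,2.1,12.54,8.6
Alouatta seniculus,1.82,0.12,0.47,0.03,0.55,0.04,34.71,6.19,25.87,7.73
Aotus vociferans,1.73,0.09,0.45,0.03,0.54,0.02,0.18,6.67,5.11,4.07
Ateles geoffroyi,1.7,0.07,0.52,0.02,0.53,0.02,18.46,12.24,0.17,3.25
Brachyteles arachnoides,1.84,0.13,0.48,0.02,0.57,0.02,33.52,8.04,22.83,8.65
Cacajao calvus,1.51,0.1,0.5,0.02,0.51,0.02,-5.75,16.34,-12.01,5.43
Callicebus discolor,1.61,0.06,0.45,0.03,0.54,0.02,-9.25,4.7,0.307,2.6
Callicebus moloch,1.65,0.04,0.46,0.02,0.53,0.01,-6.95,4.26,-3.04,4.79
Cebus capucinus,1.59,0.11,0.45,0.03,0.51,0.03,-11.74,3.98,-6.86,6.82
Chiropotes satanas,1.46,0.08,0.48,0.02,0.49,0.01,-15.4,7.37,-13.8,4.3
Lagothrix lagotricha,1.69,0.1,0.47,0.02,0.53,0.02,11.45,19.12,4.53,4.7
Pithecia irrorata,1.53,0.13,0.48,0.03,0.51,0.02,-16.67,3.28,-14.15,6.6
Saimiri boliviensis,1.85,0.09,0.47,0.01,0.53,0.02,4.82,6.28,-1.22,-5.68
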