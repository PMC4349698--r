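group,variable,mean,ci_high,ci_low
folivore,or_lower,1.8,1.85,1.74
folivore,rfi_upper,0.47,0.49,0.45
folivore,rfi_lower,0.54,0.56,0.52
folivore,sq_upper,34.54,37.26,31.81
folivore,sq_lower,20.04,24.58,15.67
frugivore,or_lower,1.7,1.73,1.67
frugivore,rfi_upper,0.47,0.48,0.46
frugivore,rfi_lower,0.53,0.53,0.52
frugivore,sq_upper,2.27,6.17,-1.62
frugivore,sq_lower,0.09,1.75,-1.56
hard_object,or_lower,1.5,1.54,1.46
hard_object,rfi_upper,0.49,0.5,0.48
hard_object,rfi_lower,0.51,0.52,0.5
hard_object,sq_upper,-12.25,-7.63,-16.87
hard_object,sq_lower,-13.25,-11.104,-15.57
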