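label,treatment,plasma,brain,csf,printed_kp,printed_kp_uu
NHP1,niraparib,84,378,9,4.530,0.446
NHP2,niraparib,436,797,25,1.829,0.180
NHP3,olaparib,322,12,13,0.037,0.024
NHP4,olaparib,254,11,6,0.044,0.028
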