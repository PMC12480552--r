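label,treatment,time_h,n,plasma,brain,tumor,note
niraparib_2h,niraparib,2,9,8627,688,7704,
niraparib_24h,niraparib,24,9,937,171,436,
olaparib_2h,olaparib,2,9,2451,76,309,
olaparib_24h,olaparib,24,9,23.5,NA,NA,brain detectable in 1/9 and tumor in 3/9 animals; ratios NC
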