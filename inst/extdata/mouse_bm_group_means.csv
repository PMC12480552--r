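label,treatment,group,n,plasma,brain,tumor,note
niraparib_noBM,niraparib,no-BM,3,3847,658,NA,
niraparib_BM,niraparib,BM,4,2535,543,2396,tumor is the MSI tumor-ROI group mean
olaparib_noBM,olaparib,no-BM,3,226,5,NA,
olaparib_BM,olaparib,BM,3,119,6,NA,tumor below MSI LOD
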