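variable,unit,family,r1_mean,r1_se,r2_mean,r2_se,mean_source,se_source
gene_16S,copies g-1 soil,lognormal,4.3e9,8.5e8,3.1e9,8.5e8,reported,synthetic
pmoA,copies g-1 soil,lognormal,9.5e4,1.1e4,2.9e4,5.0e3,reported,synthetic
nifH,copies g-1 soil,lognormal,823.33,600,3541.67,2400,reported,synthetic
dehydrogenase,ug TPF g-1 dry soil 24 h-1,normal,33.02,1.6,22.90,1.4,reported,synthetic
urease,ug NH4-N g-1 dry soil 3 h-1,normal,41.15,1.7,31.07,1.5,reported,synthetic
amylase,ug glucose g-1 dry soil 24 h-1,normal,73.84,1.5,64.81,1.4,reported,synthetic
cellulase,ug glucose g-1 dry soil 24 h-1,normal,52.4,4.0,49.8,4.0,synthetic,synthetic
MBC,ug C g-1 soil,normal,41.35,3.0,17.87,2.2,reported,synthetic
CN_ratio,ratio,normal,12.18,0.45,15.43,0.50,reported,synthetic
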