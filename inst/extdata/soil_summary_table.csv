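attribute,unit,n,mean,se,sd,min,max,cv,skewness,kurtosis
FCO2,umol m-2 s-1,900,2.91,0.06,0.56,1.83,5.28,19.33,0.87,2.17
Ts,degC,900,22.58,0.06,0.59,20.01,23.34,2.62,-1.81,4.4
Ms,%,900,16.94,0.17,1.74,13.90,21.10,10.29,0.49,-0.52
Ds,g cm-3,100,1.33,0.01,0.09,1.08,1.57,6.91,-0.25,0.55
Macro,%,100,11.08,0.48,4.80,1.95,24.62,43.35,0.75,0.17
Micro,%,100,39.55,0.48,4.82,26.37,45.82,12.18,-1.21,0.78
TPV,%,100,50.63,0.45,4.53,31.14,68.56,8.94,0.40,8.1
AFPS,%,100,33.68,0.51,5.09,12.34,54.46,15.10,0.00,6.38
Clay,%,100,61.58,0.48,4.83,50.80,68.80,7.85,-0.58,-0.78
Silt,%,100,20.23,0.34,3.36,14.96,34.23,16.62,1.29,2.36
Sand,%,100,17.20,0.16,1.57,13.40,20.36,9.11,-0.23,-0.04
SOM,g dm-3,100,32.17,0.34,3.40,24.00,43.00,10.56,0.32,0.27
Cstock,Mg ha-1,100,48.08,0.59,5.85,32.40,63.49,12.99,0.10,-0.1
k,d-1,100,0.0007,0.00,0.0002,0.0003,0.0012,23.03,0.7020,0.8224
pH,CaCl2,100,5.01,0.03,0.26,4.40,5.50,5.23,-0.24,-0.37
P,mg dm-3,100,28.13,3.21,32.08,9.00,188.00,114.05,3.06,9.39
K,cmolc dm-3,100,0.15,0.00,0.05,0.05,0.30,31.18,0.88,0.91
Ca,cmolc dm-3,100,3.36,0.26,2.64,1.01,25.15,78.54,6.19,48.07
Mg,cmolc dm-3,100,1.21,0.06,0.57,0.40,3.72,47.07,1.93,5.07
Al,cmolc dm-3,100,0.19,0.03,0.31,0.00,1.27,162.16,1.93,3.47
H_Al,cmolc dm-3,100,49.33,1.22,12.23,8.74,78.98,24.78,-0.36,0.74
SB,cmolc dm-3,100,4.72,0.31,3.13,1.54,29.00,66.26,5.30,37.4
CEC,cmolc dm-3,100,8.88,0.29,2.88,6.48,31.77,32.46,5.62,40.84
V,%,100,50.67,1.22,12.23,21.02,91.26,24.13,0.36,0.74
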