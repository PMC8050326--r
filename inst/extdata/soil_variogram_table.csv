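attribute,model,nugget,sill,sdi_class,range_m,ssr,r2,rmse,log_transformed
FCO2,spherical,1.56e-01,2.57e-01,Weak,26.74,6.33e-05,0.97,0.49,FALSE
Ts,spherical,1.51e-01,2.30e-01,Weak,25.27,9.44e-05,0.89,0.46,FALSE
Ms,spherical,5.45e-03,8.34e-03,Moderate,53.74,8.86e-07,0.80,1.52,TRUE
Ds,spherical,4.84e-03,7.52e-03,Weak,32.35,4.25e-07,0.79,0.08,FALSE
Macro,spherical,7.28e+00,1.61e+01,Moderate,24.31,2.42e+00,0.74,3.92,FALSE
Micro,spherical,1.36e+01,2.13e+01,Moderate,38.02,5.50e-01,0.98,4.40,FALSE
TPV,spherical,3.01e+00,7.00e+00,Moderate,36.97,2.27e-01,0.97,2.34,FALSE
AFPS,spherical,7.42e+00,1.67e+01,Moderate,45.00,8.80e-01,0.98,4.08,FALSE
Clay,exponential,5.02e+00,2.43e+01,Moderate,24.60,5.03e+00,0.87,4.78,FALSE
Silt,exponential,1.94e+00,7.55e+00,Moderate,22.32,5.56e-02,0.99,2.70,FALSE
Sand,spherical,3.78e-01,2.46e+00,Strong,53.98,9.79e-02,0.95,1.22,FALSE
SOM,spherical,6.89e+00,1.05e+01,Weak,30.87,5.47e-01,0.89,3.18,FALSE
Cstock,spherical,1.38e+01,2.87e+01,Moderate,26.06,1.75e+00,0.96,5.07,FALSE
k,spherical,8.50e-09,1.64e-08,Weak,21.19,1.67e-18,0.84,0.00,FALSE
pH,spherical,3.11e-02,5.71e-02,Weak,23.20,8.39e-06,0.95,0.23,FALSE
P,spherical,2.16e-02,2.49e-01,Strong,28.20,4.81e-03,0.69,12.86,TRUE
K,spherical,8.67e-04,2.02e-03,Moderate,22.32,8.37e-08,0.67,0.05,FALSE
Ca,spherical,8.44e-02,1.44e-01,Moderate,29.77,6.98e-05,0.92,1.36,TRUE
Mg,spherical,8.10e-02,1.61e-01,Moderate,25.51,1.57e-05,0.99,0.48,TRUE
Al,spherical,2.00e-02,5.57e-02,Moderate,24.06,3.39e-05,0.85,0.30,TRUE
H_Al,spherical,6.90e+01,1.15e+02,Weak,25.37,2.64e+01,0.90,10.58,FALSE
SB,spherical,7.01e-02,1.37e-01,Weak,23.19,1.29e-04,0.85,1.86,TRUE
CEC,spherical,3.86e-03,2.85e-02,Moderate,23.74,1.21e-06,0.99,1.56,TRUE
V,spherical,7.95e+01,1.39e+02,Weak,27.55,1.11e+02,0.83,11.22,FALSE
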