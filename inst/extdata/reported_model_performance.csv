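trait,pretreatment,LV,n,one_minus_vr,rmsecv,r2_v,rmsev,rpd_v,rer_v
DM,SNV-DE,10,122,0.704,0.700,0.204,1.234,1.134,6.408
NaCl,SNV-DE,10,123,0.687,0.715,NA,69.439,0.005,0.020
alpha_tocopherol,"SNV-DE SG 1,4,4,1",5,117,0.730,1.522,0.601,2.029,1.600,5.998
gamma_tocopherol,"SNV-DE SG 1,4,4,1",5,125,0.731,1.633,NA,9.454,0.028,0.169
C16:0,"SNV-DE SG 1,4,4,1",6,128,0.651,0.560,0.184,0.729,1.120,5.490
C18:0,"SNV-DE SG 1,4,4,1",6,128,0.728,0.597,0.554,0.673,1.514,6.437
C18:1 n-9,"SG 1,4,4,1",6,126,0.612,0.889,0.118,1.036,1.076,5.162
C18:2 n-6,"SG 1,4,4,1",6,129,0.652,0.206,0.386,0.259,1.291,6.112
C18:3 n-3,"SNV-DE SG 1,4,4,1",4,134,0.824,0.146,0.808,0.142,2.309,10.106
MDA,"SNV-DE SG 1,4,4,1",8,124,0.746,0.213,0.342,0.338,1.247,4.376
carbonyls,"SNV-DE SG 1,4,4,1",4,126,0.441,0.343,0.065,0.499,1.046,4.832
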