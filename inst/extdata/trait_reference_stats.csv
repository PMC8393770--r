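trait,set,n,mean,min,max,sd
DM,cal,138,73.13,69.09,78.04,1.36
NaCl,cal,138,3.58,2.91,4.46,0.32
alpha_tocopherol,cal,138,10.30,4.89,17.14,3.28
gamma_tocopherol,cal,138,0.85,0.18,1.93,0.24
C16:0,cal,138,24.64,20.65,26.44,0.92
C18:0,cal,138,11.59,5.36,12.69,1.24
C18:1 n-9,cal,138,51.00,48.71,58.50,1.50
C18:2 n-6,cal,138,5.74,5.05,7.11,0.36
C18:3 n-3,cal,138,0.59,0.29,1.53,0.30
MDA,cal,138,1.44,0.59,2.31,0.43
carbonyls,cal,138,3.30,2.02,4.54,0.52
DM,val,47,73.02,69.09,78.04,1.29
NaCl,val,47,3.55,2.98,4.46,0.33
alpha_tocopherol,val,47,10.37,4.89,17.44,3.35
gamma_tocopherol,val,47,0.85,0.18,1.93,0.24
C16:0,val,47,24.59,20.65,26.44,0.97
C18:0,val,47,11.49,5.36,12.69,1.34
C18:1 n-9,val,47,51.07,48.71,58.50,1.60
C18:2 n-6,val,47,5.75,5.05,7.11,0.38
C18:3 n-3,val,47,0.62,0.29,1.74,0.33
MDA,val,47,1.40,0.59,2.31,0.44
carbonyls,val,47,3.32,2.03,4.54,0.52
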