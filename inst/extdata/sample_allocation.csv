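set,storage_time,Black,Red,White
cal,T0,13,15,15
cal,T4,13,12,15
cal,T8,14,15,15
cal,T12,3,5,3
val,T0,5,5,5
val,T4,5,5,4
val,T8,4,4,4
val,T12,2,2,2
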