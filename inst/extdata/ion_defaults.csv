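ion_class,erev_mV,conc_in_mM,conc_out_mM,valence,temperature_C,dt_ms
Kv,-86.7,85.0,3.3152396,1,37,0.05
Nav,50.0,21.0,136.3753955,1,37,0.05
Cav,135.0,8.1929e-5,2.0,2,37,0.05
KCa,-86.7,85.0,3.3152396,1,37,0.05
Ih,-45.0,NA,NA,NA,37,0.05
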