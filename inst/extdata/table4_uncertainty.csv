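name,value_percent,type,source
Repetitive measurements,0.04,A,repeated EBT3 film readings at the reference point
Film calibration (6 MV photon beam),0.50,B,residuals of the dose-netOD cubic fit
EBT3 response at low photon energy,11.00,B,published kilovoltage-beam film response studies
Medium correction factor (CF_M),4.72,B,RMSE of the ABS-to-water conversion against direct water calculation
Geometric uncertainty (+/- 1 mm setup),0.98,B,positioning tolerance of source and film
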