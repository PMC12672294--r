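block,theta_deg,mean,sd
ebt,20,1.05,0.08
ebt,30,1.19,0.09
ebt,40,1.11,0.12
ebt,50,1.1,0.1
ebt,60,1.06,0.07
ebt,70,1.01,0.04
ebt,80,1.02,0.05
mc,0,1.16,0.04
mc,10,1.09,0.06
mc,20,1.05,0.11
mc,30,1.08,0.09
mc,40,1.01,0.11
mc,50,0.97,0.09
mc,60,1,0.09
mc,70,0.98,0.1
mc,80,1,0.06
ratio,20,0.94,0.1
ratio,30,1.07,0.06
ratio,40,1.06,0.07
ratio,50,1.09,0.08
ratio,60,1.04,0.05
ratio,70,1.04,0.1
ratio,80,1.02,0.07
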