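block,theta_deg,r_cm,value
ebt,20,2.8,1.02
ebt,20,3,0.94
ebt,20,3.2,0.98
ebt,20,3.4,1.08
ebt,20,3.6,1.02
ebt,20,3.8,1.07
ebt,20,4,1.1
ebt,20,4.2,1.21
ebt,30,2,1.05
ebt,30,2.2,1.1
ebt,30,2.4,1.1
ebt,30,2.6,1.16
ebt,30,2.8,1.2
ebt,30,3,1.13
ebt,30,3.2,1.19
ebt,30,3.4,1.32
ebt,30,3.6,1.23
ebt,30,3.8,1.21
ebt,30,4,1.33
ebt,30,4.2,1.28
ebt,40,1.6,0.94
ebt,40,1.8,0.97
ebt,40,2,0.96
ebt,40,2.2,1.03
ebt,40,2.4,1
ebt,40,2.6,1.12
ebt,40,2.8,1.14
ebt,40,3,1.07
ebt,40,3.2,1.16
ebt,40,3.4,1.19
ebt,40,3.6,1.22
ebt,40,3.8,1.18
ebt,40,4,1.32
ebt,40,4.2,1.3
ebt,50,1.4,0.92
ebt,50,1.6,1.01
ebt,50,1.8,0.99
ebt,50,2,0.97
ebt,50,2.2,1.04
ebt,50,2.4,1.04
ebt,50,2.6,1.09
ebt,50,2.8,1.16
ebt,50,3,1.1
ebt,50,3.2,1.07
ebt,50,3.4,1.18
ebt,50,3.6,1.14
ebt,50,3.8,1.2
ebt,50,4,1.24
ebt,50,4.2,1.31
ebt,60,1.2,0.94
ebt,60,1.4,0.93
ebt,60,1.6,1.01
ebt,60,1.8,1
ebt,60,2,0.99
ebt,60,2.2,1.05
ebt,60,2.4,1.02
ebt,60,2.6,1.05
ebt,60,2.8,1.08
ebt,60,3,1.08
ebt,60,3.2,1.06
ebt,60,3.4,1.11
ebt,60,3.6,1.12
ebt,60,3.8,1.11
ebt,60,4,1.21
ebt,60,4.2,1.15
ebt,70,1.1,0.93
ebt,70,1.2,0.93
ebt,70,1.4,0.98
ebt,70,1.6,0.99
ebt,70,1.8,1.01
ebt,70,2,1
ebt,70,2.2,1.02
ebt,70,2.4,1
ebt,70,2.6,1.05
ebt,70,2.8,1.11
ebt,70,3,1.05
ebt,70,3.2,1.04
ebt,70,3.4,1.05
ebt,70,3.6,1.01
ebt,70,3.8,1.02
ebt,70,4,1.03
ebt,70,4.2,1.01
ebt,80,1.1,0.97
ebt,80,1.2,0.95
ebt,80,1.4,0.99
ebt,80,1.6,0.98
ebt,80,1.8,1.01
ebt,80,2,1.01
ebt,80,2.2,1.01
ebt,80,2.4,1.01
ebt,80,2.6,1.06
ebt,80,2.8,1.09
ebt,80,3,1.03
ebt,80,3.2,1
ebt,80,3.4,1.11
ebt,80,3.6,0.98
ebt,80,3.8,0.98
ebt,80,4,1.1
ebt,80,4.2,1.13
mc,0,1,1.1
mc,0,1.1,1.11
mc,0,1.2,1.13
mc,0,1.4,1.15
mc,0,1.6,1.16
mc,0,1.8,1.17
mc,0,2,1.15
mc,0,2.2,1.17
mc,0,2.4,1.2
mc,0,2.6,1.15
mc,0,2.8,1.15
mc,0,3,1.14
mc,0,3.2,1.16
mc,0,3.4,1.17
mc,0,3.6,1.23
mc,0,3.8,1.24
mc,0,4,1.18
mc,0,4.2,1.11
mc,10,1,1.03
mc,10,1.1,1.05
mc,10,1.2,1.01
mc,10,1.4,1.05
mc,10,1.6,1.09
mc,10,1.8,1.04
mc,10,2,1.05
mc,10,2.2,1.05
mc,10,2.4,1.09
mc,10,2.6,1.07
mc,10,2.8,1.07
mc,10,3,1.03
mc,10,3.2,1.08
mc,10,3.4,1.13
mc,10,3.6,1.18
mc,10,3.8,1.18
mc,10,4,1.22
mc,10,4.2,1.12
mc,20,1,0.86
mc,20,1.1,0.9
mc,20,1.2,0.87
mc,20,1.4,0.94
mc,20,1.6,0.93
mc,20,1.8,1.06
mc,20,2,1.07
mc,20,2.2,1.05
mc,20,2.4,1.06
mc,20,2.6,1.06
mc,20,2.8,1.05
mc,20,3,1.03
mc,20,3.2,1.11
mc,20,3.4,1.19
mc,20,3.6,1.22
mc,20,3.8,1.24
mc,20,4,1.17
mc,20,4.2,1.03
mc,30,1,0.97
mc,30,1.1,0.89
mc,30,1.2,0.95
mc,30,1.4,0.96
mc,30,1.6,1.1
mc,30,1.8,1.07
mc,30,2,1.04
mc,30,2.2,1.01
mc,30,2.4,1.12
mc,30,2.6,1.08
mc,30,2.8,1.06
mc,30,3,1.12
mc,30,3.2,1.15
mc,30,3.4,1.14
mc,30,3.6,1.18
mc,30,3.8,1.19
mc,30,4,1.2
mc,30,4.2,1.13
mc,40,1,0.83
mc,40,1.1,0.77
mc,40,1.2,0.85
mc,40,1.4,0.98
mc,40,1.6,0.86
mc,40,1.8,0.98
mc,40,2,1
mc,40,2.2,0.98
mc,40,2.4,1.01
mc,40,2.6,1.06
mc,40,2.8,1.08
mc,40,3,1.05
mc,40,3.2,1.1
mc,40,3.4,1.13
mc,40,3.6,1.15
mc,40,3.8,1.13
mc,40,4,1.13
mc,40,4.2,1.06
mc,50,1,0.83
mc,50,1.1,0.76
mc,50,1.2,0.83
mc,50,1.4,0.97
mc,50,1.6,0.86
mc,50,1.8,0.99
mc,50,2,0.98
mc,50,2.2,0.97
mc,50,2.4,0.98
mc,50,2.6,1.02
mc,50,2.8,1.01
mc,50,3,0.99
mc,50,3.2,1.02
mc,50,3.4,1
mc,50,3.6,1.08
mc,50,3.8,1.08
mc,50,4,1.09
mc,50,4.2,1.04
mc,60,1,0.91
mc,60,1.1,0.84
mc,60,1.2,0.89
mc,60,1.4,0.89
mc,60,1.6,1.01
mc,60,1.8,0.99
mc,60,2,0.96
mc,60,2.2,0.93
mc,60,2.4,1.03
mc,60,2.6,0.99
mc,60,2.8,0.96
mc,60,3,1.04
mc,60,3.2,1.08
mc,60,3.4,1.04
mc,60,3.6,1.08
mc,60,3.8,1.16
mc,60,4,1.17
mc,60,4.2,1.04
mc,70,1,0.89
mc,70,1.1,0.83
mc,70,1.2,0.89
mc,70,1.4,0.86
mc,70,1.6,0.86
mc,70,1.8,0.99
mc,70,2,0.98
mc,70,2.2,0.95
mc,70,2.4,0.96
mc,70,2.6,0.92
mc,70,2.8,0.93
mc,70,3,0.95
mc,70,3.2,1.01
mc,70,3.4,1.07
mc,70,3.6,1.15
mc,70,3.8,1.17
mc,70,4,1.14
mc,70,4.2,1.03
mc,80,1,0.93
mc,80,1.1,0.94
mc,80,1.2,0.92
mc,80,1.4,0.95
mc,80,1.6,0.96
mc,80,1.8,0.96
mc,80,2,0.97
mc,80,2.2,0.99
mc,80,2.4,1.03
mc,80,2.6,1.03
mc,80,2.8,1
mc,80,3,1.03
mc,80,3.2,1.06
mc,80,3.4,1.06
mc,80,3.6,1.11
mc,80,3.8,1.1
mc,80,4,1.07
mc,80,4.2,0.97
ratio,20,2.8,0.97
ratio,20,3,0.92
ratio,20,3.2,0.88
ratio,20,3.4,0.91
ratio,20,3.6,0.84
ratio,20,3.8,0.86
ratio,20,4,0.94
ratio,20,4.2,1.17
ratio,30,2,1.02
ratio,30,2.2,1.09
ratio,30,2.4,0.98
ratio,30,2.6,1.07
ratio,30,2.8,1.13
ratio,30,3,1.01
ratio,30,3.2,1.03
ratio,30,3.4,1.16
ratio,30,3.6,1.04
ratio,30,3.8,1.02
ratio,30,4,1.11
ratio,30,4.2,1.13
ratio,40,1.6,1.09
ratio,40,1.8,0.99
ratio,40,2,0.96
ratio,40,2.2,1.05
ratio,40,2.4,0.99
ratio,40,2.6,1.06
ratio,40,2.8,1.06
ratio,40,3,1.02
ratio,40,3.2,1.06
ratio,40,3.4,1.05
ratio,40,3.6,1.06
ratio,40,3.8,1.05
ratio,40,4,1.17
ratio,40,4.2,1.23
ratio,50,1.4,0.95
ratio,50,1.6,1.17
ratio,50,1.8,1
ratio,50,2,0.99
ratio,50,2.2,1.07
ratio,50,2.4,1.06
ratio,50,2.6,1.07
ratio,50,2.8,1.15
ratio,50,3,1.11
ratio,50,3.2,1.05
ratio,50,3.4,1.18
ratio,50,3.6,1.06
ratio,50,3.8,1.11
ratio,50,4,1.14
ratio,50,4.2,1.26
ratio,60,1.2,1.05
ratio,60,1.4,1.05
ratio,60,1.6,1
ratio,60,1.8,1.01
ratio,60,2,1.02
ratio,60,2.2,1.13
ratio,60,2.4,1
ratio,60,2.6,1.06
ratio,60,2.8,1.13
ratio,60,3,1.03
ratio,60,3.2,0.99
ratio,60,3.4,1.07
ratio,60,3.6,1.04
ratio,60,3.8,0.95
ratio,60,4,1.03
ratio,60,4.2,1.1
ratio,70,1.1,1.12
ratio,70,1.2,1.05
ratio,70,1.4,1.14
ratio,70,1.6,1.15
ratio,70,1.8,1.01
ratio,70,2,1.02
ratio,70,2.2,1.07
ratio,70,2.4,1.05
ratio,70,2.6,1.15
ratio,70,2.8,1.19
ratio,70,3,1.11
ratio,70,3.2,1.03
ratio,70,3.4,0.99
ratio,70,3.6,0.88
ratio,70,3.8,0.87
ratio,70,4,0.9
ratio,70,4.2,0.99
ratio,80,1.1,1.04
ratio,80,1.2,1.03
ratio,80,1.4,1.04
ratio,80,1.6,1.02
ratio,80,1.8,1.05
ratio,80,2,1.04
ratio,80,2.2,1.02
ratio,80,2.4,0.98
ratio,80,2.6,1.03
ratio,80,2.8,1.09
ratio,80,3,1
ratio,80,3.2,0.94
ratio,80,3.4,1.04
ratio,80,3.6,0.88
ratio,80,3.8,0.89
ratio,80,4,1.03
ratio,80,4.2,1.17
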