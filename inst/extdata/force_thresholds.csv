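joint,sex,min_kgf,max_kgf,coef_p05,coef_p95
lumbar,male,44.6,65.1,0.87,1.16
cervical,male,6.8,8.8,0.82,1.20
shoulder,male,4.2,13.6,0.96,1.05
elbow,male,1.9,11.6,0.98,1.02
wrist,male,0.5,10.6,0.99,1.01
knee,male,36.9,80.6,0.83,1.18
lumbar,female,27.7,46.9,0.90,1.13
cervical,female,5.5,7.1,0.83,1.21
shoulder,female,3.1,12.7,0.96,1.04
elbow,female,1.4,11.2,0.98,1.02
wrist,female,0.4,10.5,0.99,1.01
knee,female,27.2,60.4,0.84,1.18
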