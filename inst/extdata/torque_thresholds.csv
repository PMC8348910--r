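joint,sex,min_kgm,max_kgm,coef_p05,coef_p95
lumbar,male,1.81,22.95,0.82,1.22
cervical,male,0.15,0.90,0.73,1.32
shoulder,male,0.49,5.85,0.92,1.09
elbow,male,0.33,3.20,0.93,1.08
wrist,male,0.04,0.83,0.97,1.03
knee,male,3.73,26.34,0.86,1.41
lumbar,female,1.08,15.92,0.85,1.20
cervical,female,0.11,0.62,0.72,1.35
shoulder,female,0.34,5.15,0.93,1.09
elbow,female,0.23,2.81,0.93,1.08
wrist,female,0.03,0.70,0.97,1.03
knee,female,2.32,17.66,0.84,1.44
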