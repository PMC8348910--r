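segment,sex,weight_pct,cg_pct,p05_x,p05_y,p05_z,p50_x,p50_y,p50_z,p95_x,p95_y,p95_z
pelvis,male,12.42,50.0,0.065,0.105,0.105,0.091,0.148,0.148,0.122,0.199,0.190
lumbar,male,13.60,50.0,0.065,0.105,0.105,0.091,0.148,0.148,0.122,0.199,0.199
thorax,male,23.19,49.7,0.052,0.075,0.075,0.073,0.106,0.106,0.098,0.142,0.142
head,male,8.39,30.0,0.027,0.014,0.027,0.038,0.019,0.038,0.051,0.026,0.051
arm,male,2.77,38.0,0.002,0.019,0.019,0.003,0.027,0.027,0.004,0.036,0.036
forearm,male,1.73,49.5,0.001,0.014,0.014,0.001,0.020,0.020,0.001,0.027,0.027
hand,male,0.65,80.0,0.001,0.001,0.003,0.001,0.001,0.004,0.001,0.001,0.005
thigh,male,10.49,53.2,0.069,0.017,0.069,0.097,0.024,0.097,0.130,0.032,0.130
shin,male,4.28,49.8,0.006,0.001,0.006,0.008,0.001,0.008,0.011,0.001,0.011
foot,male,1.28,50.0,0.005,0.005,0.001,0.007,0.007,0.001,0.009,0.009,0.001
pelvis,female,16.72,50.0,0.052,0.083,0.086,0.075,0.120,0.123,0.106,0.169,0.174
lumbar,female,11.02,50.0,0.031,0.050,0.051,0.045,0.072,0.074,0.064,0.102,0.104
thorax,female,15.55,49.7,0.021,0.031,0.031,0.030,0.044,0.044,0.042,0.062,0.062
head,female,9.13,30.0,0.017,0.009,0.017,0.025,0.013,0.025,0.035,0.018,0.035
arm,female,2.85,37.9,0.001,0.012,0.012,0.002,0.017,0.017,0.003,0.024,0.024
forearm,female,1.71,49.6,0.001,0.009,0.009,0.001,0.013,0.013,0.001,0.018,0.018
hand,female,0.69,80.0,0.001,0.001,0.001,0.001,0.001,0.002,0.001,0.001,0.003
thigh,female,12.57,53.0,0.049,0.013,0.049,0.071,0.018,0.071,0.100,0.025,0.100
shin,female,4.53,49.4,0.003,0.001,0.003,0.005,0.001,0.005,0.007,0.001,0.007
foot,female,1.44,50.0,0.003,0.003,0.001,0.004,0.005,0.001,0.006,0.007,0.001
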