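joint,slow_speed,max_speed,slow_accel,max_accel
lumbar,10,51,50,255
cervical,41,223,205,1115
shoulder,53,247,265,1235
elbow,54,233,270,1165
wrist,66,224,330,1120
knee,40,133,200,665
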