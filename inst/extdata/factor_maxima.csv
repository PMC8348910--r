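joint,angle_max,accel_max,force_max,torque_max,grip_max
lumbar,2.0,1.5,2.0,2.5,1.0
cervical,2.0,1.5,2.0,2.5,1.0
shoulder,2.0,1.5,2.0,2.5,1.0
elbow,2.0,1.5,2.0,2.5,1.0
wrist,1.6,1.5,2.0,2.5,2.0
knee,2.0,1.5,2.0,2.5,1.0
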