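joint,axis,angle_deg,score
lumbar,Rx,-20,2.0
lumbar,Rx,0,1.0
lumbar,Rx,20,1.0
lumbar,Rx,60,2.0
lumbar,Ry,-40,2.0
lumbar,Ry,-10,1.0
lumbar,Ry,10,1.0
lumbar,Ry,40,2.0
lumbar,Rz,-30,2.0
lumbar,Rz,-10,1.0
lumbar,Rz,10,1.0
lumbar,Rz,30,2.0
cervical,Rx,-20,2.0
cervical,Rx,0,1.0
cervical,Rx,10,1.0
cervical,Rx,30,2.0
cervical,Ry,-50,2.0
cervical,Ry,-20,1.0
cervical,Ry,20,1.0
cervical,Ry,50,2.0
cervical,Rz,-30,2.0
cervical,Rz,-10,1.0
cervical,Rz,10,1.0
cervical,Rz,30,2.0
elbow,Rx,0,1.5
elbow,Rx,60,1.0
elbow,Rx,100,1.0
elbow,Rx,150,2.0
elbow,Ry,-90,1.5
elbow,Ry,-30,1.0
elbow,Ry,30,1.0
elbow,Ry,90,1.5
wrist,Rx,-45,1.6
wrist,Rx,-15,1.0
wrist,Rx,15,1.0
wrist,Rx,45,1.6
wrist,Ry,-20,1.6
wrist,Ry,-5,1.0
wrist,Ry,5,1.0
wrist,Ry,20,1.6
wrist,Rz,-20,1.6
wrist,Rz,-5,1.0
wrist,Rz,5,1.0
wrist,Rz,20,1.6
knee,Rx,-10,2.0
knee,Rx,0,1.0
knee,Rx,30,1.0
knee,Rx,90,2.0
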