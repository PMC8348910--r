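elevation,anteroposterior,score
0,-90,2.00
0,-20,1.25
0,0,1.00
0,20,1.00
0,45,1.25
0,90,1.50
0,180,2.00
20,-90,2.00
20,-20,1.25
20,0,1.00
20,20,1.00
20,45,1.25
20,90,1.50
20,180,2.00
45,-90,2.00
45,-20,1.25
45,0,1.25
45,20,1.25
45,45,1.25
45,90,1.50
45,180,2.00
90,-90,2.00
90,-20,1.50
90,0,1.50
90,20,1.50
90,45,1.50
90,90,1.50
90,180,2.00
120,-90,2.00
120,-20,2.00
120,0,2.00
120,20,2.00
120,45,2.00
120,90,2.00
120,180,2.00
180,-90,2.00
180,-20,2.00
180,0,2.00
180,20,2.00
180,45,2.00
180,90,2.00
180,180,2.00
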