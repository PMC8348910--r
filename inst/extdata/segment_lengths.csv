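segment,stature_fraction
pelvis,0.078
lumbar,0.112
thorax,0.150
head,0.130
arm,0.188
forearm,0.145
hand,0.108
thigh,0.245
shin,0.246
foot,0.152
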