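rpm_lo,rpm_hi,level_lo,level_hi,valuation,interpretation,color
0,10,0,1,No risk,Acceptable,#4caf50
10,15,1,2,Low risk,Acceptable,#8bc34a
15,25,2,3,Medium risk,Acceptable,#ffc107
25,40,3,4,High risk,Conditional,#ff9800
40,70,4,5,Very high risk,Unacceptable,#f44336
70,Inf,5,Inf,Severe risk,Unacceptable,#b71c1c
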