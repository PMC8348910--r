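code,label,score
0,Not specified,1.0
1,Appropriate wrap,1.3
2,Unprepared wrap,1.8
3,Appropriate hook,1.3
4,Reasonably appropriate hook,1.6
5,Unprepared hook,1.9
6,Pinch,1.3
7,Precision pinch,1.6
8,Appropriate open hand,1.7
9,Unprepared open hand,2.0
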