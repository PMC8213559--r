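stimulus,x,y,Y
1,0.303,0.307,1.0
2,0.308,0.314,1.8
3,0.311,0.317,3.2
4,0.314,0.321,5.7
5,0.313,0.322,10.0
6,0.315,0.322,17.9
7,0.314,0.321,32.0
8,0.315,0.322,57.2
9,0.313,0.320,100.0
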