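subject,trial,LR,MSt,TSt,PSw,Sw
A,1,-32,134,9,-85,-14
A,2,-5,121,14,-94,-1
A,3,-47,139,2,-75,6
B,1,18,17,21,-64,-30
B,2,43,42,26,-40,-41
B,3,48,29,17,-40,-38
C,1,-30,97,15,-65,11
C,2,-26,102,18,-51,8
C,3,-23,104,7,-56,10
D,1,48,38,27,-43,-39
D,2,22,21,22,-60,-27
D,3,43,34,18,-39,-39
E,1,-25,91,18,-61,13
E,2,-25,98,13,-55,12
E,3,-22,100,19,-47,12
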