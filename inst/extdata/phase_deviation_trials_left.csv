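subject,trial,LR,MSt,TSt,PSw,Sw
A,1,10,115,13,-98,5
A,2,-40,140,5,-86,-21
A,3,-71,148,8,-97,20
B,1,34,38,15,-42,-44
B,2,12,39,-3,-61,-40
B,3,59,29,5,-45,-46
C,1,-14,101,-20,-50,8
C,2,-35,99,20,-75,5
C,3,-29,99,-11,-52,0
D,1,23,34,-6,-56,-39
D,2,32,37,11,-45,-43
D,3,47,41,12,-50,-40
E,1,-25,69,-18,-38,-9
E,2,-29,84,-14,-48,-12
E,3,-13,80,4,-44,-1
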