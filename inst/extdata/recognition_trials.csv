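path,trial,walking_forward,walking_backwards,lateral_left,lateral_right,turning_left,turning_right,sitting_down,standing_up
A,1,100,0,0,0,0,0,0,0
A,2,99.23,0,0,0,0,0,0,0.77
A,3,100,0,0,0,0,0,0,0
A,4,100,0,0,0,0,0,0,0
A,5,99.09,0,0,0,0.04,0,0,0.87
A,6,98.94,0,0,0,0,0,0,1.06
A,7,100,0,0,0,0,0,0,0
A,8,99.16,0,0,0,0.09,0,0,0.75
A,9,100,0,0,0,0,0,0,0
A,10,100,0,0,0,0,0,0,0
B,1,81.14,0,0,0,10.30,7.03,0,1.53
B,2,77.45,0,0,0,11.19,10.84,0,0.52
B,3,79.38,0,0,0,9.92,9.76,0,0.94
B,4,85.18,0,0,0,8.97,5.75,0,0.10
B,5,81.83,0,0,0,10.45,7.28,0,0.44
B,6,79.92,0,0,0,11.90,7.87,0,0.31
B,7,81.67,0,0.06,0,9.82,8.00,0,0.45
B,8,78.21,0,0,0,11.37,9.36,0,1.06
B,9,80.12,0,0.05,0,11.26,8.13,0,0.44
B,10,79.60,0,0,0,10.16,9.37,0,0.87
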