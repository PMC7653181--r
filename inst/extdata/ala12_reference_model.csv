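S0,S1,S2,S3,S4,S5,state,stationary,lifetime
0.610,0.276,0.038,0.031,0.036,0.009,S0,0.114,2.61
0.170,0.693,0.021,0.037,0.026,0.053,S1,0.187,3.30
0.042,0.037,0.758,0.115,0.030,0.018,S2,0.103,4.16
0.032,0.064,0.109,0.725,0.050,0.020,S3,0.109,3.67
0.031,0.038,0.024,0.042,0.798,0.067,S4,0.131,4.97
0.003,0.027,0.005,0.006,0.025,0.934,S5,0.356,15.15
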