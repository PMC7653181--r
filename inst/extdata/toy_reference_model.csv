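S0,S1,S2,state,stationary,lifetime
0.882,0.069,0.049,S0,0.184,8.5
0.024,0.858,0.118,S1,0.532,7.08
0.032,0.221,0.747,S2,0.284,3.99
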