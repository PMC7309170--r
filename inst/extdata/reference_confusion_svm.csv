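class,A01,A02,A03,A04,A05,A06,A07,A08,A09,SUM,Recall
A01,6552,34,0,44,0,0,0,0,0,6630,0.988235
A02,0,6417,25,33,0,0,0,0,0,6475,0.991042
A03,5,5,6510,0,0,0,0,0,0,6520,0.998466
A04,0,2,114,5621,110,123,84,125,246,6425,0.874864
A05,0,0,0,243,5966,117,43,19,27,6415,0.930008
A06,0,0,0,108,123,5852,120,86,196,6485,0.90239
A07,0,0,0,32,0,13,6354,56,0,6455,0.984353
A08,0,0,0,54,51,25,71,6146,66,6413,0.958366
A09,0,0,0,352,186,174,76,213,1944,2945,0.660102
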