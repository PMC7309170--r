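class,A01,A02,A03,A04,A05,A06,A07,A08,A09,SUM,Recall
A01,6603,17,10,0,0,0,0,0,0,6630,0.995928
A02,0,6475,0,0,0,0,0,0,0,6475,1
A03,6,3,6511,0,0,0,0,0,0,6520,0.99862
A04,0,21,1,5741,72,72,88,76,354,6425,0.893541
A05,0,0,12,121,5798,139,109,114,122,6415,0.903819
A06,0,0,13,241,345,5336,154,267,129,6485,0.822822
A07,0,0,0,25,44,57,6300,24,5,6455,0.975988
A08,0,0,2,31,20,40,51,6147,122,6413,0.958522
A09,0,0,0,120,206,162,167,133,2157,2945,0.732428
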