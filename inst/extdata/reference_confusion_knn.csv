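class,A01,A02,A03,A04,A05,A06,A07,A08,A09,SUM,Recall
A01,6617,0,8,5,0,0,0,0,0,6630,0.998039
A02,0,6475,0,0,0,0,0,0,0,6475,1
A03,4,12,6504,0,0,0,0,0,0,6520,0.997546
A04,0,67,19,5552,76,114,24,169,404,6425,0.864125
A05,0,0,22,188,5644,139,213,114,95,6415,0.879813
A06,0,0,13,355,345,5124,213,267,168,6485,0.790131
A07,0,0,0,51,67,0,6289,41,7,6455,0.974284
A08,0,0,0,19,0,0,12,6312,70,6413,0.984251
A09,0,0,0,220,206,162,167,245,1945,2945,0.660441
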