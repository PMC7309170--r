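class,A01,A02,A03,A04,A05,A06,A07,A08,A09,SUM,Recall
A01,6618,4,8,0,0,0,0,0,0,6630,0.99819
A02,0,6475,0,0,0,0,0,0,0,6475,1
A03,22,41,6457,0,0,0,0,0,0,6520,0.990337
A04,0,0,22,6014,67,0,122,67,133,6425,0.936031
A05,0,0,0,154,5848,46,77,41,249,6415,0.911613
A06,0,0,0,188,205,5622,169,105,196,6485,0.866924
A07,0,0,0,10,4,0,6375,22,44,6455,0.987607
A08,0,0,0,70,14,0,42,6254,33,6413,0.975207
A09,0,0,7,122,105,91,78,25,2517,2945,0.854669
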