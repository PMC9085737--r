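element,rstar,eps
C,1.9080,0.1094
N,1.8240,0.1700
O,1.6612,0.2100
S,2.0000,0.2500
P,2.1000,0.2000
H,0.6000,0.0157
SE,2.0000,0.2500
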