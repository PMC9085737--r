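aa,class
D,charged
E,charged
K,charged
R,charged
H,charged
N,polar
Q,polar
S,polar
T,polar
Y,polar
W,polar
C,polar
A,apolar
G,apolar
F,apolar
I,apolar
L,apolar
M,apolar
P,apolar
V,apolar
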