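resid,atom,charge
SER,CB,0.40
SER,OG,-0.40
THR,CB,0.40
THR,OG1,-0.40
CYS,CB,0.20
CYS,SG,-0.20
TYR,CZ,0.40
TYR,OH,-0.40
ASN,CG,0.50
ASN,OD1,-0.50
GLN,CD,0.50
GLN,OE1,-0.50
ASP,CG,0.40
ASP,OD1,-0.70
ASP,OD2,-0.70
GLU,CD,0.40
GLU,OE1,-0.70
GLU,OE2,-0.70
LYS,NZ,1.00
ARG,CZ,0.60
ARG,NH1,0.20
ARG,NH2,0.20
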