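resname,atom,class
*,N,DONOR
*,O,ACCEPTOR
*,OXT,NEGATIVE
*,OXT,ACCEPTOR
ARG,NE,POSITIVE
ARG,NE,DONOR
ARG,NH1,POSITIVE
ARG,NH1,DONOR
ARG,NH2,POSITIVE
ARG,NH2,DONOR
LYS,NZ,POSITIVE
LYS,NZ,DONOR
HIS,ND1,POSITIVE
HIS,ND1,DONOR
HIS,ND1,ACCEPTOR
HIS,NE2,POSITIVE
HIS,NE2,DONOR
HIS,NE2,ACCEPTOR
ASP,OD1,NEGATIVE
ASP,OD1,ACCEPTOR
ASP,OD2,NEGATIVE
ASP,OD2,ACCEPTOR
GLU,OE1,NEGATIVE
GLU,OE1,ACCEPTOR
GLU,OE2,NEGATIVE
GLU,OE2,ACCEPTOR
SER,OG,DONOR
SER,OG,ACCEPTOR
THR,OG1,DONOR
THR,OG1,ACCEPTOR
TYR,OH,DONOR
TYR,OH,ACCEPTOR
TRP,NE1,DONOR
ASN,ND2,DONOR
ASN,OD1,ACCEPTOR
GLN,NE2,DONOR
GLN,OE1,ACCEPTOR
CYS,SG,DONOR
MET,SD,ACCEPTOR
HOH,O,DONOR
HOH,O,ACCEPTOR
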