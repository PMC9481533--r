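# Per-residue ordering-entropy penalty, kcal/mol, applied to each scored
# residue (degrees of freedom lost on going from a disordered to an ordered,
# fibril-bound state). Conventional side-chain TdS-at-300K magnitudes;
# editable, identity stamped into output metadata. Penalties must be >= 0.
residue	penalty
GLY	0.00
ALA	0.00
SER	1.19
CYS	1.20
THR	1.09
VAL	0.85
LEU	0.76
ILE	0.89
MET	1.77
PRO	0.60
PHE	0.86
TYR	1.08
TRP	0.88
ASP	1.25
GLU	1.81
ASN	1.46
GLN	2.02
LYS	2.21
ARG	2.57
HIS	0.99
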