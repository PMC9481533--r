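# Synthetic ring-definition convention for an EGCG-like flavan-3-ol gallate:
# A = benzenediol ring, B = pyrogallol ring, C = tetrahydropyran ring,
# D = galloyl ring. Atom names follow a generic flavan numbering and MUST be
# checked against the chemical component entry used in your model (override
# with ringDefinitions(path)). The mock fixture ligand instead uses rings
# named via mockLigandRings().
ring	atom
A	C4A
A	C5
A	C6
A	C7
A	C8
A	C8A
B	C1'
B	C2'
B	C3'
B	C4'
B	C5'
B	C6'
C	O1
C	C2
C	C3
C	C4
C	C4A
C	C8A
D	C1G
D	C2G
D	C3G
D	C4G
D	C5G
D	C6G
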