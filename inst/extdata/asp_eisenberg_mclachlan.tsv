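# Atomic solvation parameters, cal/mol/A^2, by heavy-atom class
# (Eisenberg-McLachlan atom-class scale). Editable; the table identity is
# stamped into every SolvationEnergyMap's metadata.
class	asp
C	16
N/O	-6
O-	-24
N+	-50
S	21
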