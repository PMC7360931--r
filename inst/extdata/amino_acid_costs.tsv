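# Per-amino-acid energetic accounting.
# side_chain_carbons: carbon atoms in the side chain (counted from the structural formula; Gly = H side chain = 0).
# phosphate_cost: high-energy phosphate bonds (~P) per molecule synthesized, aerobic Escherichia coli values
#   from Akashi H, Gojobori T (2002) PNAS 99:3695-3700, Table 1.
amino_acid	side_chain_carbons	phosphate_cost
A	1	11.7
R	4	27.3
N	2	14.7
D	2	12.7
C	1	24.7
Q	3	16.3
E	3	15.3
G	0	11.7
H	4	38.3
I	4	32.3
L	4	27.3
K	4	30.3
M	3	34.3
F	7	52.0
P	3	20.3
S	1	11.7
T	2	18.7
W	9	74.3
Y	7	50.0
V	3	23.3
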