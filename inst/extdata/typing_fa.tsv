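# Full-atom (FA) primitive typing rules.
# Columns: residue <TAB> ptype <TAB> mode <TAB> atoms (comma-separated).
# residue "*" matches any canonical residue (backbone rules).
# Every heavy atom of the 20 canonical amino acids must be covered by
# exactly one rule; residue-specific rules take precedence over "*" rules.
# Special case handled in code: in a residue carrying OXT, the backbone O
# is promoted to O_neg (the C-terminal carboxylate O/OXT pair).
# Chemistry defaults assume physiological pH: Arg/Lys protonated (N_pos),
# Asp/Glu deprotonated (O_neg), His neutral (ring N -> N_neu, ring C ->
# C_aro). FA has no carbonyl-carbon type: backbone C and the carboxyl/amide
# side-chain carbons are C_ali.
residue	ptype	mode	atoms
*	N_neu	atom	N
*	C_ali	atom	CA,C,CB
*	O_neu	atom	O
*	O_neg	atom	OXT
ARG	C_ali	atom	CG,CD,CZ
ARG	N_pos	atom	NE,NH1,NH2
ASN	C_ali	atom	CG
ASN	O_neu	atom	OD1
ASN	N_neu	atom	ND2
ASP	C_ali	atom	CG
ASP	O_neg	atom	OD1,OD2
CYS	S	atom	SG
GLN	C_ali	atom	CG,CD
GLN	O_neu	atom	OE1
GLN	N_neu	atom	NE2
GLU	C_ali	atom	CG,CD
GLU	O_neg	atom	OE1,OE2
HIS	C_aro	atom	CG,CD2,CE1
HIS	N_neu	atom	ND1,NE2
ILE	C_ali	atom	CG1,CG2,CD1
LEU	C_ali	atom	CG,CD1,CD2
LYS	C_ali	atom	CG,CD,CE
LYS	N_pos	atom	NZ
MET	C_ali	atom	CG,CE
MET	S	atom	SD
PHE	C_aro	atom	CG,CD1,CD2,CE1,CE2,CZ
PRO	C_ali	atom	CG,CD
SER	O_neu	atom	OG
THR	O_neu	atom	OG1
THR	C_ali	atom	CG2
TRP	C_aro	atom	CG,CD1,CD2,CE2,CE3,CZ2,CZ3,CH2
TRP	N_neu	atom	NE1
TYR	C_aro	atom	CG,CD1,CD2,CE1,CE2,CZ
TYR	O_neu	atom	OH
VAL	C_ali	atom	CG1,CG2
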