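# Coarse-grained (CG) primitive typing rules.
# Columns: residue <TAB> ptype <TAB> mode <TAB> atoms (comma-separated).
# mode "atom": one primitive per listed atom present, at the atom position.
# mode "group": one primitive at the unweighted geometric center of the
# listed atoms that are present (skipped only if none are present).
# Atoms not covered by any rule are omitted from the primitive cloud
# (e.g. backbone N and O, amide O/N of Asn and Gln).
# Special case handled in code: in a residue carrying OXT, an O,OXT group
# centroid is emitted as a Neg site (C-terminal carboxylate).
residue	ptype	mode	atoms
*	AmideC	atom	C
*	Ali	atom	CA,CB
ARG	Ali	atom	CG,CD
ARG	Pos	group	CZ,NE,NH1,NH2
ASN	AmideC	atom	CG
ASP	Ali	atom	CG
ASP	Neg	group	OD1,OD2
CYS	S	atom	SG
GLN	Ali	atom	CG
GLN	AmideC	atom	CD
GLU	Ali	atom	CG,CD
GLU	Neg	group	OE1,OE2
HIS	Aro	group	CG,ND1,CD2,CE1,NE2
ILE	Ali	atom	CG1,CG2,CD1
LEU	Ali	atom	CG,CD1,CD2
LYS	Ali	atom	CG,CD,CE
LYS	Pos	atom	NZ
MET	Ali	atom	CG,CE
MET	S	atom	SD
PHE	Aro	group	CG,CD1,CD2,CE1,CE2,CZ
PRO	Ali	atom	CG,CD
SER	OH	atom	OG
THR	OH	atom	OG1
THR	Ali	atom	CG2
TRP	Aro	group	CG,CD1,CD2,NE1,CE2
TRP	Aro	group	CD2,CE2,CE3,CZ2,CZ3,CH2
TYR	Aro	group	CG,CD1,CD2,CE1,CE2,CZ
TYR	OH	atom	OH
VAL	Ali	atom	CG1,CG2
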