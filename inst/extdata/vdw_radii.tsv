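# abitope default van der Waals radii table ("chothia76" style, as used by
# classic accessibility programs). Columns: res_name, atom_name, radius_A.
#   res_name "*"       -> rule applies to the named atom in any residue
#   res_name "ELEMENT" -> fallback by element symbol (atom_name = element)
# Trigonal/aromatic carbons 1.76 A; tetrahedral carbons 1.87 A;
# all N 1.65 A; all O 1.40 A; S 1.85 A. Probe radius is a parameter of the
# SASA computation (default 1.4 A), not of this table.
res_name	atom_name	radius_A
*	C	1.76
ARG	CZ	1.76
ASP	CG	1.76
ASN	CG	1.76
GLU	CD	1.76
GLN	CD	1.76
HIS	CG	1.76
HIS	CD2	1.76
HIS	CE1	1.76
PHE	CG	1.76
PHE	CD1	1.76
PHE	CD2	1.76
PHE	CE1	1.76
PHE	CE2	1.76
PHE	CZ	1.76
TYR	CG	1.76
TYR	CD1	1.76
TYR	CD2	1.76
TYR	CE1	1.76
TYR	CE2	1.76
TYR	CZ	1.76
TRP	CG	1.76
TRP	CD1	1.76
TRP	CD2	1.76
TRP	CE2	1.76
TRP	CE3	1.76
TRP	CZ2	1.76
TRP	CZ3	1.76
TRP	CH2	1.76
ELEMENT	C	1.87
ELEMENT	N	1.65
ELEMENT	O	1.40
ELEMENT	S	1.85
ELEMENT	P	1.80
ELEMENT	SE	1.90
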