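# Region map for the IgSF V-set domain of human PD-L1 (author numbering,
# construct aa 18-134). Strand/loop boundaries follow the canonical V-set
# topology designation; exact boundary residues are an editorial choice of
# this package. Non-overlapping ranges; residues outside every range are
# labelled "unassigned".
region	start	end
nterm	18	22
strand_A	23	32
strand_B	33	42
BC_loop	43	53
strand_C	54	59
CC_loop	60	65
strand_Cp	66	67
CpCpp_loop	68	72
strand_Cpp	73	76
strand_D	77	84
DE_loop	85	87
strand_E	88	95
EF_loop	96	109
strand_F	110	117
FG_loop	118	120
strand_G	121	130
cterm	131	134
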