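# Steryl residues resolved by mass; M398 and M412 are mass-ambiguous groups
# (M398: 24-methylenecholesterol / d5,24-ergostadienol; M412: stigmasterol /
# putative methylenepollinastanol / isofucosterol / 24-methylenelophenol),
# modeled as single grouped residues.
name	C	H	O
cholesterol	27	46	1
campesterol	28	48	1
sitosterol	29	50	1
M398	28	46	1
M412	29	48	1
cycloeucalenol	30	50	1
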