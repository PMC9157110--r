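# Lipid subclass registry.
# backbone (bb_*) and headgroup (hg_*) element counts are those of the free
# (uncondensed) molecules; species formulas subtract one H2O per
# condensation bond. Sphingolipid backbones are empty because the sphingoid
# base chain itself is the backbone; sterol backbones come from the steryl
# residue pool.
name	category	n_chains	ionization	bb_C	bb_H	bb_N	bb_O	bb_P	bb_S	hg_C	hg_H	hg_N	hg_O	hg_P	hg_S
PC	glycerophospholipid	2	positive	3	8	0	3	0	0	5	14	1	4	1	0
PE	glycerophospholipid	2	positive	3	8	0	3	0	0	2	8	1	4	1	0
PA	glycerophospholipid	2	negative	3	8	0	3	0	0	0	3	0	4	1	0
PI	glycerophospholipid	2	negative	3	8	0	3	0	0	6	13	0	9	1	0
PS	glycerophospholipid	2	negative	3	8	0	3	0	0	3	8	1	6	1	0
PG	glycerophospholipid	2	negative	3	8	0	3	0	0	3	9	0	6	1	0
PIP	glycerophospholipid	2	negative	3	8	0	3	0	0	6	14	0	12	2	0
PIP2	glycerophospholipid	2	negative	3	8	0	3	0	0	6	15	0	15	3	0
MGDG	galactoglycerolipid	2	positive	3	8	0	3	0	0	6	12	0	6	0	0
DGDG	galactoglycerolipid	2	positive	3	8	0	3	0	0	12	22	0	11	0	0
SQDG	galactoglycerolipid	2	negative	3	8	0	3	0	0	6	12	0	8	0	1
MG	neutral glycerolipid	1	positive	3	8	0	3	0	0	0	0	0	0	0	0
DG	neutral glycerolipid	2	positive	3	8	0	3	0	0	0	0	0	0	0	0
TG	neutral glycerolipid	3	positive	3	8	0	3	0	0	0	0	0	0	0	0
LPC	lyso-glycerophospholipid	1	positive	3	8	0	3	0	0	5	14	1	4	1	0
LPE	lyso-glycerophospholipid	1	positive	3	8	0	3	0	0	2	8	1	4	1	0
LPA	lyso-glycerophospholipid	1	negative	3	8	0	3	0	0	0	3	0	4	1	0
LPI	lyso-glycerophospholipid	1	negative	3	8	0	3	0	0	6	13	0	9	1	0
LPS	lyso-glycerophospholipid	1	negative	3	8	0	3	0	0	3	8	1	6	1	0
LPG	lyso-glycerophospholipid	1	negative	3	8	0	3	0	0	3	9	0	6	1	0
SPB	sphingolipid	1	positive	0	0	0	0	0	0	0	0	0	0	0	0
SPBP	sphingolipid	1	positive	0	0	0	0	0	0	0	3	0	4	1	0
Cer	sphingolipid	2	positive	0	0	0	0	0	0	0	0	0	0	0	0
CerP	sphingolipid	2	positive	0	0	0	0	0	0	0	3	0	4	1	0
HexCer	sphingolipid	2	positive	0	0	0	0	0	0	6	12	0	6	0	0
IPC	sphingolipid	2	negative	0	0	0	0	0	0	6	13	0	9	1	0
GlcA-IPC	sphingolipid	2	negative	0	0	0	0	0	0	12	21	0	15	1	0
HexNAc-GlcA-IPC	sphingolipid	2	negative	0	0	0	0	0	0	20	34	1	20	1	0
Hex-HexNAc-GlcA-IPC	sphingolipid	2	negative	0	0	0	0	0	0	26	44	1	25	1	0
FS	sterol_lipid	0	positive	0	0	0	0	0	0	0	0	0	0	0	0
SE	sterol_lipid	1	positive	0	0	0	0	0	0	0	0	0	0	0	0
SG	sterol_lipid	0	positive	0	0	0	0	0	0	6	12	0	6	0	0
ASG	sterol_lipid	1	positive	0	0	0	0	0	0	6	12	0	6	0	0
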