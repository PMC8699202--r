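# pepccs residue chemistry table, version 1
# One row per residue symbol of the 21-letter internal alphabet (20 standard
# amino acids + 'm' = methionine sulfoxide, i.e. oxidized Met).
# Element counts are RESIDUE compositions (free amino acid minus H2O).
# Class flags follow the shipped default class sets; note that the non-polar
# set is read as {G,A,V,L,I,P,M,F,W} (see package documentation for the
# ambiguity this resolves). Oxidized Met carries only the 'modified' and
# 'uncharged_polar' flags and inherits Met's six float descriptors.
# Descriptor columns (stand-in scales, user-replaceable). All descriptors
# must be NON-NEGATIVE: the share-type cumulative feature divides a window
# sum by the full-sequence sum, and signed scales can cancel that
# denominator to near zero, producing unbounded feature values.
#   hydropathy  shifted Kyte-Doolittle (1982) hydropathy index (original + 4.5)
#   volume      Zamyatnin (1972) residue volume, A^3
#   polarity    Grantham (1974) polarity
#   pi          isoelectric point of the free amino acid
#   helix       Chou-Fasman (1978) alpha-helix propensity P_alpha
#   bulkiness   Zimmerman (1968) bulkiness
symbol	name	index	H	C	N	O	S	acidic	modified	amide	nonpolar	small	uncharged_polar	aliphatic	aromatic	positive	hydroxyl	dyad_ND	dyad_EQ	hydropathy	volume	polarity	pi	helix	bulkiness
A	Ala	0	5	3	1	1	0	0	0	0	1	1	0	1	0	0	0	0	0	6.3	88.6	8.1	6.00	1.42	11.50
C	Cys	1	5	3	1	1	1	0	0	0	0	0	1	0	0	0	0	0	0	7.0	108.5	5.5	5.07	0.70	13.46
D	Asp	2	5	4	1	3	0	1	0	0	0	0	0	0	0	0	0	1	0	1.0	111.1	13.0	2.77	1.01	11.68
E	Glu	3	7	5	1	3	0	1	0	0	0	0	0	0	0	0	0	0	1	1.0	138.4	12.3	3.22	1.51	13.57
F	Phe	4	9	9	1	1	0	0	0	0	1	0	0	0	1	0	0	0	0	7.3	189.9	5.2	5.48	1.13	19.80
G	Gly	5	3	2	1	1	0	0	0	0	1	1	0	1	0	0	0	0	0	4.1	60.1	9.0	5.97	0.57	3.40
H	His	6	7	6	3	1	0	0	0	0	0	0	0	0	0	1	0	0	0	1.3	153.2	10.4	7.59	1.00	13.69
I	Ile	7	11	6	1	1	0	0	0	0	1	0	0	1	0	0	0	0	0	9.0	166.7	5.2	6.02	1.08	21.40
K	Lys	8	12	6	2	1	0	0	0	0	0	0	0	0	0	1	0	0	0	0.6	168.6	11.3	9.74	1.16	15.71
L	Leu	9	11	6	1	1	0	0	0	0	1	0	0	1	0	0	0	0	0	8.3	166.7	4.9	5.98	1.21	21.40
M	Met	10	9	5	1	1	1	0	0	0	1	0	0	0	0	0	0	0	0	6.4	162.9	5.7	5.74	1.45	16.25
N	Asn	11	6	4	2	2	0	0	0	1	0	0	1	0	0	0	0	1	0	1.0	114.1	11.6	5.41	0.67	12.82
P	Pro	12	7	5	1	1	0	0	0	0	1	1	0	0	0	0	0	0	0	2.9	112.7	8.0	6.30	0.57	17.43
Q	Gln	13	8	5	2	2	0	0	0	1	0	0	1	0	0	0	0	0	1	1.0	143.8	10.5	5.65	1.11	14.45
R	Arg	14	12	6	4	1	0	0	0	0	0	0	0	0	0	1	0	0	0	0.0	173.4	10.5	10.76	0.98	14.28
S	Ser	15	5	3	1	2	0	0	0	0	0	1	1	0	0	0	1	0	0	3.7	89.0	9.2	5.68	0.77	9.47
T	Thr	16	7	4	1	2	0	0	0	0	0	0	1	0	0	0	1	0	0	3.8	116.1	8.6	5.60	0.83	15.77
V	Val	17	9	5	1	1	0	0	0	0	1	0	0	1	0	0	0	0	0	8.7	140.0	5.9	5.96	1.06	21.57
W	Trp	18	10	11	2	1	0	0	0	0	1	0	0	0	1	0	0	0	0	3.6	227.8	5.4	5.89	1.08	21.67
Y	Tyr	19	9	9	1	2	0	0	0	0	0	0	1	0	1	0	1	0	0	3.2	193.6	6.2	5.66	0.69	18.03
m	MetOx	20	9	5	1	2	1	0	1	0	0	0	1	0	0	0	0	0	0	6.4	162.9	5.7	5.74	1.45	16.25
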