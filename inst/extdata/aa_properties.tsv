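aa	name	logP	pI
A	Alanine	-3.0	6.01
R	Arginine	-4.2	10.76
N	Asparagine	-3.8	5.41
D	Aspartate	-3.9	2.77
C	Cysteine	-2.5	5.07
Q	Glutamine	-3.6	5.65
E	Glutamate	-3.7	3.22
G	Glycine	-3.2	5.97
H	Histidine	-3.3	7.59
I	Isoleucine	-1.7	6.02
L	Leucine	-1.5	5.98
K	Lysine	-3.1	9.74
M	Methionine	-1.9	5.74
F	Phenylalanine	-1.4	5.48
P	Proline	-2.5	6.48
S	Serine	-3.1	5.68
T	Threonine	-2.9	5.87
W	Tryptophan	-1.1	5.89
Y	Tyrosine	-2.3	5.66
V	Valine	-2.3	5.97
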