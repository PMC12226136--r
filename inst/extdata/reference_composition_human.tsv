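residue	percent
A	7
R	5.6
N	3.6
D	4.7
C	2.3
Q	4.8
E	7.1
G	6.6
H	2.6
I	4.3
L	10
K	5.7
M	2.1
F	3.7
P	6.3
S	8.3
T	5.4
W	1.2
Y	2.7
V	6
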