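residue	frequency
A	0.0780780780780781
C	0.019019019019019
D	0.0540540540540541
E	0.0630630630630631
F	0.039039039039039
G	0.0740740740740741
H	0.022022022022022
I	0.051051051051051
K	0.0570570570570571
L	0.0910910910910911
M	0.022022022022022
N	0.045045045045045
P	0.0520520520520521
Q	0.043043043043043
R	0.051051051051051
S	0.0710710710710711
T	0.0580580580580581
V	0.0640640640640641
W	0.013013013013013
Y	0.032032032032032
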