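# Four-class physicochemical scheme. Tryptophan (W) is kept in the
# hydrophobic class: the complete 20-residue listing includes it there,
# and the partition must assign every residue exactly once.
aa	class
A	hydrophobic
V	hydrophobic
F	hydrophobic
P	hydrophobic
M	hydrophobic
I	hydrophobic
L	hydrophobic
W	hydrophobic
S	polar_uncharged
Y	polar_uncharged
N	polar_uncharged
Q	polar_uncharged
C	polar_uncharged
T	polar_uncharged
H	polar_uncharged
G	polar_uncharged
D	acidic
E	acidic
K	basic
R	basic
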