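aa	class
A	nonpolar
V	nonpolar
L	nonpolar
I	nonpolar
P	nonpolar
F	nonpolar
M	nonpolar
W	nonpolar
G	nonpolar
S	polar
T	polar
C	polar
Y	polar
N	polar
Q	polar
D	acidic
E	acidic
K	basic
R	basic
H	basic
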