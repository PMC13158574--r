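onset
P
B
T
D
K
G
F
V
TH
DH
S
Z
SH
CH
JH
M
N
L
R
W
Y
HH
P L
P R
P Y
B L
B R
B Y
T R
T W
D R
D W
K L
K R
K W
K Y
G L
G R
G W
F L
F R
F Y
V Y
TH R
TH W
SH R
HH Y
M Y
N Y
S P
S T
S K
S F
S M
S N
S L
S W
S P L
S P R
S P Y
S T R
S T Y
S K R
S K W
S K Y
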