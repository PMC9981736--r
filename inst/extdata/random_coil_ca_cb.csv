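restype,CA,CB
A,52.8,19.3
R,56.5,30.9
N,53.3,39.1
D,54.4,41.1
C,58.6,28.3
Q,56.2,29.5
E,56.8,30.3
G,45.4,NA
H,55.8,29.9
I,61.6,38.9
L,55.5,42.5
K,56.7,33.0
M,55.8,32.9
F,58.1,39.8
P,63.7,32.2
S,58.7,64.1
T,62.0,69.8
W,57.6,29.8
Y,58.3,39.0
V,62.6,32.8
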