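residue_type,atom,helix_delta,strand_delta
A,CA,2.8,-1.5
A,CB,-0.5,2.2
A,CO,1.8,-1
C,CA,2.8,-1.5
C,CB,-0.5,2.2
C,CO,1.8,-1
D,CA,2.8,-1.5
D,CB,-0.5,2.2
D,CO,1.8,-1
E,CA,2.8,-1.5
E,CB,-0.5,2.2
E,CO,1.8,-1
F,CA,2.8,-1.5
F,CB,-0.5,2.2
F,CO,1.8,-1
G,CA,2.8,-1.5
G,CO,1.8,-1
H,CA,2.8,-1.5
H,CB,-0.5,2.2
H,CO,1.8,-1
I,CA,2.8,-1.5
I,CB,-0.5,2.2
I,CO,1.8,-1
K,CA,2.8,-1.5
K,CB,-0.5,2.2
K,CO,1.8,-1
L,CA,2.8,-1.5
L,CB,-0.5,2.2
L,CO,1.8,-1
M,CA,2.8,-1.5
M,CB,-0.5,2.2
M,CO,1.8,-1
N,CA,2.8,-1.5
N,CB,-0.5,2.2
N,CO,1.8,-1
P,CA,2.8,-1.5
P,CB,-0.5,2.2
P,CO,1.8,-1
Q,CA,2.8,-1.5
Q,CB,-0.5,2.2
Q,CO,1.8,-1
R,CA,2.8,-1.5
R,CB,-0.5,2.2
R,CO,1.8,-1
S,CA,2.8,-1.5
S,CB,-0.5,2.2
S,CO,1.8,-1
T,CA,2.8,-1.5
T,CB,-0.5,2.2
T,CO,1.8,-1
V,CA,2.8,-1.5
V,CB,-0.5,2.2
V,CO,1.8,-1
W,CA,2.8,-1.5
W,CB,-0.5,2.2
W,CO,1.8,-1
Y,CA,2.8,-1.5
Y,CB,-0.5,2.2
Y,CO,1.8,-1
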