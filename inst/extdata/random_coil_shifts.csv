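residue_type,atom,shift_ppm
A,CA,52.6
A,CB,19
A,CO,177.7
A,H,8.24
A,N,123.8
C,CA,58.3
C,CB,28.2
C,CO,174.8
C,H,8.32
C,N,118.8
D,CA,54.1
D,CB,40.8
D,CO,176.3
D,H,8.34
D,N,120.4
E,CA,56.7
E,CB,30.1
E,CO,176.5
E,H,8.42
E,N,120.2
F,CA,57.9
F,CB,39.3
F,CO,175.9
F,H,8.3
F,N,120.3
G,CA,45.3
G,CO,174
G,H,8.33
G,N,108.8
H,CA,55.3
H,CB,29.3
H,CO,174.9
H,H,8.42
H,N,118.2
I,CA,61.6
I,CB,38.6
I,CO,176.5
I,H,8
I,N,119.9
K,CA,56.5
K,CB,32.7
K,CO,176.5
K,H,8.29
K,N,120.4
L,CA,55.4
L,CB,42.2
L,CO,177.1
L,H,8.16
L,N,121.8
M,CA,55.6
M,CB,32.8
M,CO,176.3
M,H,8.28
M,N,119.6
N,CA,53
N,CB,38.7
N,CO,175.2
N,H,8.38
N,N,118.7
P,CA,63.3
P,CB,32
P,CO,176.9
Q,CA,55.8
Q,CB,29.5
Q,CO,175.8
Q,H,8.32
Q,N,119.8
R,CA,56.1
R,CB,30.6
R,CO,176.3
R,H,8.23
R,N,120.5
S,CA,58.6
S,CB,63.8
S,CO,174.6
S,H,8.31
S,N,115.7
T,CA,62
T,CB,69.7
T,CO,174.6
T,H,8.15
T,N,113.6
V,CA,62.5
V,CB,32.6
V,CO,176.2
V,H,8.03
V,N,119.2
W,CA,57.6
W,CB,29.5
W,CO,176.2
W,H,8.25
W,N,121.3
Y,CA,58
Y,CB,38.8
Y,CO,175.8
Y,H,8.12
Y,N,120.3
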