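patient_id,biologic,printed_relative_pasi
A,ust,100
A,ada,19
B,ada,-7
B,ust,99
C,ust,8
C,ada,96
D,ada,-100
D,ust,89
E,ada,52
E,gus,46
E,sec,85
F,gol,90
F,ada,80
G,ust,60
G,sec,89
G,ixe,100
H,ada,26
H,ust,69
H,sec,93
I,ada,47
I,sec,100
J,ust,100
J,ixe,92
K,ust,75
K,ixe,100
L,ust,89
L,ixe,94
M,ada,74
M,sec,94
N,ust,89
N,gol,66
N,ixe,100
O,sec,49
O,ust,84
P,ixe,100
P,gus,100
Q,ust,92.5
Q,gus,100
R,ust,100
R,ris,100
S,ust,42
S,ixe,100
T,ust,80
T,ris,93
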