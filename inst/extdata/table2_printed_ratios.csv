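patient_id,condition_kind,biologic,index,printed_value
A,induced,,IFN-g/IL-13,3.27
A,induced_plus_biologic,ada,IFN-g/IL-13,3.46
A,induced_plus_biologic,ust,IFN-g/IL-13,3.36
B,induced,,IFN-g/IL-13,62.47
B,induced_plus_biologic,ada,IFN-g/IL-13,108.99
B,induced_plus_biologic,ust,IFN-g/IL-13,57.27
B,induced,,IFN-g/IL-4,13.44
B,induced_plus_biologic,ada,IFN-g/IL-4,24.8
B,induced_plus_biologic,ust,IFN-g/IL-4,13.03
C,induced,,IFN-g/IL-13,45.8
C,induced_plus_biologic,ada,IFN-g/IL-13,33.41
C,induced_plus_biologic,ust,IFN-g/IL-13,43.94
C,induced,,IFN-g/IL-4,3.81
C,induced_plus_biologic,ada,IFN-g/IL-4,4.14
C,induced_plus_biologic,ust,IFN-g/IL-4,3.92
D,induced,,IFN-g/IL-13,38.61
D,induced_plus_biologic,ada,IFN-g/IL-13,51.53
D,induced_plus_biologic,ust,IFN-g/IL-13,38.19
D,induced,,IFN-g/IL-4,14.38
D,induced_plus_biologic,ada,IFN-g/IL-4,16.28
D,induced_plus_biologic,ust,IFN-g/IL-4,13.93
E,induced,,IFN-g/IL-13,60.52
E,induced_plus_biologic,ada,IFN-g/IL-13,50.32
E,induced_plus_biologic,gus,IFN-g/IL-13,63.56
E,induced_plus_biologic,sec,IFN-g/IL-13,46.85
E,induced,,IFN-g/IL-4,7.61
E,induced_plus_biologic,ada,IFN-g/IL-4,8.18
E,induced_plus_biologic,gus,IFN-g/IL-4,6.9
E,induced_plus_biologic,sec,IFN-g/IL-4,6.19
F,induced,,IFN-g/IL-13,33.69
F,induced_plus_biologic,ada,IFN-g/IL-13,47.39
F,induced_plus_biologic,gol,IFN-g/IL-13,48.5
F,induced,,IFN-g/IL-4,9.85
F,induced_plus_biologic,ada,IFN-g/IL-4,12.2
F,induced_plus_biologic,gol,IFN-g/IL-4,12.35
G,induced,,IFN-g/IL-13,11.86
G,induced_plus_biologic,ixe,IFN-g/IL-13,13.49
G,induced_plus_biologic,ust,IFN-g/IL-13,15.2
G,induced_plus_biologic,sec,IFN-g/IL-13,10.89
G,induced,,IFN-g/IL-4,8.53
G,induced_plus_biologic,ixe,IFN-g/IL-4,6.97
G,induced_plus_biologic,ust,IFN-g/IL-4,8.94
G,induced_plus_biologic,sec,IFN-g/IL-4,7.38
H,induced,,IFN-g/IL-13,31.27
H,induced_plus_biologic,ust,IFN-g/IL-13,30.76
H,induced_plus_biologic,ada,IFN-g/IL-13,50.45
H,induced_plus_biologic,sec,IFN-g/IL-13,26.35
H,induced,,IFN-g/IL-4,7.55
H,induced_plus_biologic,ust,IFN-g/IL-4,7.83
H,induced_plus_biologic,ada,IFN-g/IL-4,10.54
H,induced_plus_biologic,sec,IFN-g/IL-4,5.96
I,induced,,IFN-g/IL-13,80.31
I,induced_plus_biologic,ada,IFN-g/IL-13,106.28
I,induced_plus_biologic,sec,IFN-g/IL-13,63.01
I,induced,,IFN-g/IL-4,22.83
I,induced_plus_biologic,ada,IFN-g/IL-4,26.82
I,induced_plus_biologic,sec,IFN-g/IL-4,20.54
J,induced,,IFN-g/IL-13,127.33
J,induced_plus_biologic,ixe,IFN-g/IL-13,132.63
J,induced_plus_biologic,ust,IFN-g/IL-13,119.85
J,induced,,IFN-g/IL-4,23.32
J,induced_plus_biologic,ixe,IFN-g/IL-4,24.41
J,induced_plus_biologic,ust,IFN-g/IL-4,22.33
K,induced,,IFN-g/IL-13,59.9
K,induced_plus_biologic,ust,IFN-g/IL-13,62.41
K,induced_plus_biologic,ixe,IFN-g/IL-13,61.11
K,induced,,IFN-g/IL-4,27.22
K,induced_plus_biologic,ust,IFN-g/IL-4,27.48
K,induced_plus_biologic,ixe,IFN-g/IL-4,27.75
L,induced,,IFN-g/IL-13,98.41
L,induced_plus_biologic,ust,IFN-g/IL-13,83.24
L,induced_plus_biologic,ixe,IFN-g/IL-13,56.57
L,induced,,IFN-g/IL-4,13.7
L,induced_plus_biologic,ust,IFN-g/IL-4,11.68
L,induced_plus_biologic,ixe,IFN-g/IL-4,8.17
M,induced,,IFN-g/IL-13,144.54
M,induced_plus_biologic,ada,IFN-g/IL-13,127.24
M,induced_plus_biologic,sec,IFN-g/IL-13,76.3
M,induced,,IFN-g/IL-4,31.81
M,induced_plus_biologic,ada,IFN-g/IL-4,26.83
M,induced_plus_biologic,sec,IFN-g/IL-4,19.64
N,induced,,IFN-g/IL-13,37.71
N,induced_plus_biologic,ust,IFN-g/IL-13,35.2
N,induced_plus_biologic,gol,IFN-g/IL-13,46.01
N,induced_plus_biologic,ixe,IFN-g/IL-13,34.26
N,induced,,IFN-g/IL-4,17.37
N,induced_plus_biologic,ust,IFN-g/IL-4,17.65
N,induced_plus_biologic,gol,IFN-g/IL-4,19.28
N,induced_plus_biologic,ixe,IFN-g/IL-4,16.55
O,induced,,IFN-g/IL-13,173.52
O,induced_plus_biologic,ust,IFN-g/IL-13,231.1
O,induced_plus_biologic,sec,IFN-g/IL-13,151.11
O,induced,,IFN-g/IL-4,17.03
O,induced_plus_biologic,ust,IFN-g/IL-4,16.15
O,induced_plus_biologic,sec,IFN-g/IL-4,16.14
P,induced,,IFN-g/IL-13,30.12
P,induced_plus_biologic,ixe,IFN-g/IL-13,32.08
P,induced_plus_biologic,gus,IFN-g/IL-13,21.87
P,induced,,IFN-g/IL-4,15.48
P,induced_plus_biologic,ixe,IFN-g/IL-4,15.62
P,induced_plus_biologic,gus,IFN-g/IL-4,13.51
Q,induced,,IFN-g/IL-13,200.6
Q,induced_plus_biologic,ust,IFN-g/IL-13,71.3
Q,induced_plus_biologic,gus,IFN-g/IL-13,100.8
Q,induced,,IFN-g/IL-4,13.7
Q,induced_plus_biologic,ust,IFN-g/IL-4,17.2
Q,induced_plus_biologic,gus,IFN-g/IL-4,12.9
R,induced,,IFN-g/IL-13,164.3
R,induced_plus_biologic,ust,IFN-g/IL-13,104.3
R,induced_plus_biologic,ris,IFN-g/IL-13,97.5
R,induced,,IFN-g/IL-4,21.2
R,induced_plus_biologic,ust,IFN-g/IL-4,31.3
R,induced_plus_biologic,ris,IFN-g/IL-4,22.1
S,induced,,IFN-g/IL-13,85.3
S,induced_plus_biologic,ust,IFN-g/IL-13,84
S,induced_plus_biologic,ixe,IFN-g/IL-13,138.2
S,induced,,IFN-g/IL-4,7.14
S,induced_plus_biologic,ust,IFN-g/IL-4,7.21
S,induced_plus_biologic,ixe,IFN-g/IL-4,7
T,induced,,IFN-g/IL-13,97.67
T,induced_plus_biologic,ust,IFN-g/IL-13,158.9
T,induced_plus_biologic,ris,IFN-g/IL-13,49.96
T,induced,,IFN-g/IL-4,20.4
T,induced_plus_biologic,ust,IFN-g/IL-4,13.1
T,induced_plus_biologic,ris,IFN-g/IL-4,13.99
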