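patient_id,biologic,order_index,pasi_before,pasi_after,months_to_outcome,tested_before_start
A,ust,1,3.2,0,10,FALSE
A,ada,2,3.2,2.6,6,FALSE
B,ada,1,15,16,6,FALSE
B,ust,2,15,0.2,6,FALSE
C,ust,1,13,12,6,FALSE
C,ada,2,13,0.5,6,FALSE
D,ada,1,7.5,15,12,FALSE
D,ust,2,7.5,0.8,6,TRUE
E,ada,1,25,12,26,FALSE
E,gus,2,8,4.3,6,FALSE
E,sec,3,8,1.2,6,TRUE
F,gol,1,4.1,0.4,29,FALSE
F,ada,2,4.1,0.8,6,TRUE
G,ust,1,56.5,22.4,54,FALSE
G,sec,2,22.4,2.4,20,FALSE
G,ixe,3,31.2,0,6,TRUE
H,ada,1,15.5,11.4,52,FALSE
H,ust,2,11.4,3.5,24,FALSE
H,sec,3,15.3,1,15,FALSE
I,ada,1,3.8,2,47,FALSE
I,sec,2,2,0,6,FALSE
J,ust,1,16,0,24,FALSE
J,ixe,2,15,1.2,6,FALSE
K,ust,1,15,3.7,24,FALSE
K,ixe,2,11.7,0,6,FALSE
L,ust,1,36.8,4,24,FALSE
L,ixe,2,16,1,6,FALSE
M,ada,1,20,5.2,27,FALSE
M,sec,2,16,0.9,18,FALSE
N,ust,1,27,3.1,24,FALSE
N,gol,2,27,9.1,19,FALSE
N,ixe,3,27,0,10,FALSE
O,sec,2,19.2,9.8,6,FALSE
O,ust,3,19.2,3,30,FALSE
P,ixe,1,13.1,0,6,FALSE
P,gus,2,13.1,0,20,FALSE
Q,ust,1,16,1.2,24,FALSE
Q,gus,2,27,0,33,FALSE
R,ust,1,26,0,24,FALSE
R,ris,2,16.4,0,21,FALSE
S,ust,1,7.8,4.5,24,FALSE
S,ixe,2,8.5,0,12,FALSE
T,ust,1,18.4,3.6,12,FALSE
T,ris,2,18.4,1.2,12,FALSE
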