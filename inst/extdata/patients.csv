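patient_id,age,sex,pso,psa,comorbidities
A,52,M,TRUE,FALSE,
B,43,M,TRUE,TRUE,Alcoholic hepatitis;TAILS
C,44,M,TRUE,FALSE,
D,59,M,TRUE,TRUE,
E,51,M,TRUE,TRUE,
F,55,F,TRUE,TRUE,
G,44,M,TRUE,TRUE,
H,65,F,TRUE,TRUE,
I,57,F,TRUE,TRUE,TAILS
J,40,M,TRUE,FALSE,
K,54,M,TRUE,FALSE,HBV
L,42,M,TRUE,FALSE,
M,65,F,TRUE,FALSE,Tb
N,54,M,TRUE,TRUE,
O,39,M,TRUE,TRUE,Kikuchi-Fujimoto disease;MI
P,43,M,TRUE,FALSE,HTN;CKD
Q,32,M,TRUE,TRUE,
R,42,M,TRUE,FALSE,
S,43,M,TRUE,FALSE,Hyperlipidemia
T,43,M,TRUE,FALSE,
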