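stage,T,N,M,behaviour
0,Tis,N0,M0,2
IA,T1;T1a;T1b;T1c;T1mi,N0,M0,3
IB,T0;T1;T1a;T1b;T1c;T1mi,N1mi,M0,3
IIA,T0;T1;T1a;T1b;T1c;T1mi,N1,M0,3
IIA,T2,N0,M0,3
IIB,T2,N1,M0,3
IIB,T3,N0,M0,3
IIIA,T0;T1;T1a;T1b;T1c;T1mi;T2,N2,M0,3
IIIA,T3,N1;N2,M0,3
IIIB,T4;T4a;T4b;T4c;T4d,N0;N1;N2,M0,3
IIIC,ANY,N3,M0,3
IV,ANY,ANY,M1,3
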