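haplogroup	position	alt
H	16060	C
H	16067	C
H	16074	C
HV	16081	C
HV	16088	C
HV	16095	C
V	16102	C
V	16109	C
V	16116	C
V	15204	C
J	16123	C
J	16130	C
J	16137	C
J	3394	C
J	4216	C
J	15257	A
T	16144	C
T	16151	C
T	16158	C
T	4216	C
T	4917	G
U	16165	C
U	16172	C
U	16179	C
U	5460	A
K	16186	C
K	16193	C
K	16200	C
K	14798	C
I	16207	C
I	16214	C
I	16221	C
I	11969	A
W	16228	C
W	16235	C
W	16242	C
W	12811	C
X	16249	C
X	16256	C
X	16263	C
X	13780	G
N	16270	C
N	16277	C
N	16284	C
N	15812	A
R	16291	C
R	16298	C
R	16305	C
C	16312	C
C	16319	C
C	16326	C
C	8584	A
D	16333	C
D	16340	C
D	16347	C
D	8414	T
G	16354	C
G	16361	C
G	16368	C
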