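id,ingredient,s1,s2,s3
1,Emodin,+,+,+
2,Chrysophanol,+,+,+
3,Chrysarobin,none,none,+
4,Rhein,+,+,+
5,Danthron,+,none,+
6,Polygonumnolide C2,none,none,+
7,Emodin dianthrone,none,none,+
8,Aloe emodin,+,+,none
9,Luteolin,none,+,none
10,Physcion,+,+,none
11,Apigenin,+,none,none
12,Emodin-8-methyl ether,+,none,none
13,Citreorosein,+,none,none
14,Emodin-3-methyl ether,+,none,none
15,Fallacinol,+,none,none
16,2-Acetylemodin,+,none,none
17,Hexadecanoic acid methyl ester,+,none,none
18,Octadecanoic acid methyl ester,+,none,none
19,Docosanoic acid methyl ester,+,none,none
20,4-Hydroxybenzaldehyde,+,none,none
21,"2,5-dimethyl-7-hydroxychromone",+,none,none
22,Hydroxymaltol,+,none,none
23,Butanedioic acid,+,none,none
24,"Emodin-6,8-dimethylether",+,none,none
25,Hexanoic acid,+,none,none
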