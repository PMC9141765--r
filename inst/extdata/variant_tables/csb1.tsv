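# element: CSB1
# reference: CTATATGGTATTATTGTCTTAATGCTTGGTAGACATAT
type_id	n_species	dot_pattern	species
1	12	......................................	L. agilis;L. bilineata;L. viridis viridis;Ph. kulzeri;Po. muralis;Ps. algirus;T. kuehnei;T. amurensis;T. septentrionalis;T. sylvaticus;T. wolteri;Z. vivipara
2	13	...............C.T....................	D. armeniaca;D. caucasica;D. chlorogaster;D. daghestanica;D. dahli;D. derjugini;D. mixta;D. parvula;D. portschinskii;D. raddei;D. rudis;D. unisexualis;D. valentini
3	2	...............TC..G..................	Mer. squamulosus;Pe. laticeps
4	1	...............TC.....................	Po. siculus
5	1	...............TCT.G........C.........	Mes. olivieri
6	1	....T........C.TCA....................	E. stummeri
7	1	............G..C.T....................	D. praticola
8	1	.........G......C..G..................	E. vermiculata
9	2	................GA....................	Ac. aureus;Ac. boskianus
10	2	............G.........................	D. brauneri;D. saxicola
11	2	...................G..................	E. scripta;E. nikolskii
12	3	....T..............G..................	E. dzungarica;E. przewalskii;E. yarkandensis
13	1	.........G......A..G..................	E. argus
14	1	........GGC.......G...................	E. brenchleyi
15	1	....T....G.........G..................	E. multiocellata
16	1	....T..........TA..G..................	E. szczerbaki
17	1	.....A...............................A	Ac. guineensis
18	1	.................A..........A.........	Ac. schmidti
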