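# element: TAS2
# reference: CATACATTAA
# note: the source table prints some substitution letters at columns where
# the letter equals the reference base, which is inconsistent with dot
# notation (and, for types 23/26, with the statement that exactly one taxon
# carries the reference motif). Such letters are normalised to dots where
# that keeps the row distinct, and otherwise treated as column slips and
# shifted to the nearest column keeping all rows distinct:
# type 20 "....T..T.." -> "....T....T", type 23 "...A..T..." ->
# "....AT....", type 26 ".....A...." -> "......A...".
type_id	n_species	dot_pattern	species
1	1	..........	L. viridis viridis
2	13	T..G......	D. armeniaca;D. brauneri;D. daghestanica;D. dahli;D. mixta;D. parvula;D. portschinskii;D. rudis;D. saxicola;D. valentini;E. przewalskii;L. agilis;Po. siculus
3	5	T.........	D. derjugini;D. raddei;E. yarkandensis;Ph. kulzeri;L. bilineata
4	5	T........T	Ac. schmidti;E. dzungarica;E. nikolskii;E. szczerbaki;Po. muralis
5	2	T...T.....	D. chlorogaster;D. clarkorum
6	1	T...A.....	T. amurensis
7	1	T........C	D. unisexualis
8	1	T......A.T	Ac. erythrurus
9	1	T..C......	D. caucasica
10	3	A........T	Ac. boskianus;E. multiocellata;E. stummeri
11	1	AG........	Ac. guineensis
12	1	A.........	E. vermiculata
13	1	.........T	Ac. aureus
14	2	...G......	Au. australis;Pe. laticeps
15	1	...GT.....	Mes. olivieri
16	1	.G........	Z. vivipara
17	1	....T...T.	Al. nigropunctatus
18	2	....T.....	T. septentrionalis;T. wolteri
19	1	.....T....	T. sexlineatus
20	1	....T....T	T. sylvaticus
21	1	....AC..G.	D. praticola
22	1	...C.GA...	E. argus
23	1	....AT....	E. brenchleyi
24	1	.......A.T	E. scripta
25	1	........C.	Ps. algirus
26	1	......A...	T. kuehnei
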