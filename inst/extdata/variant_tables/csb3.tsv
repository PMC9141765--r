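# element: CSB3
# reference: TCGCCAAACCCCTAAAACGA
# note: the source table prints type 8 with letters G (column 3) and A
# (column 7) equal to the reference bases at those columns; they are
# normalised to dots (the expanded motif is unchanged).
type_id	n_species	dot_pattern	species
1	36	....................	Au. australis;D. brauneri;D. chlorogaster;D. clarkorum;D. daghestanica;D. dahli;D. derjugini;D. mixta;D. parvula;D. portschinskii;D. praticola;D. raddei;D. rudis;D. saxicola;D. unisexualis;D. valentini;E. dzungarica;E. scripta KZL15;E. scripta KZL44;E. multiocellata;E. przewalskii;E. stummeri;E. szczerbaki;E. yarkandensis;L. agilis;L. bilineata;L. viridis viridis;Ph. kulzeri;Po. muralis;Po. siculus;T. amurensis;T. kuehnei;T. septentrionalis;T. sylvaticus;T. wolteri;Z. vivipara
2	5	............A.......	Ac. aureus;Ac. boskianus;Ac. schmidti;Mer. squamulosus;Pe. laticeps
3	1	...T......A.........	D. armeniaca
4	1	........T...........	E. nikolskii
5	1	C.......TT..CG....C.	E. argus
6	1	..........T.G.....A.	E. brenchleyi
7	1	........T.....G...AG	E. vermiculata
8	1	AG.....TT......T.T..	Ps. algirus
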