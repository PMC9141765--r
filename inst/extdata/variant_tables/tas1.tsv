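# element: TAS1
# reference: ACTATTATGTATATAGTGCATTAA
# note: the source table prints type 7 with a letter A at the final column,
# where the reference base is already A; the letter is normalised to a dot
# (the expanded motif is unchanged).
type_id	n_species	dot_pattern	species
1	27	........................	Al. nigropunctatus;D. armeniaca;D. brauneri;D. chlorogaster;D. daghestanica;D. dahli;D. derjugini;D. mixta;D. parvula;D. portschinskii;D. raddei;D. rudis;D. saxicola;D. unisexualis;D. valentini;E. nikolskii;E. przewalskii;L. agilis;L. bilineata;L. viridis viridis;Ph. kulzeri;Po. muralis;Po. siculus;T. kuehnei;T. septentrionalis;T. sylvaticus;T. wolteri
2	11	.................A......	Ac. aureus;Ac. boskianus;Ac. erythrurus;Ac. guineensis;Ac. schmidti;Au. australis;E. scripta;E. multiocellata;E. stummeri;E. vermiculata;E. yarkandensis
3	1	.......C.G......C......C	E. argus
4	1	..............T..A......	E. brenchleyi
5	1	..............C..A......	E. szczerbaki
6	1	..AT.........AT..A......	Mes. olivieri
7	1	..A............T......C.	Pe. laticeps
8	1	..AT...................G	Ps. algirus
9	1	....C...................	Z. vivipara
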