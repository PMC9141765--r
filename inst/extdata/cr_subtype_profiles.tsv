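# Synthetic layout profiles for the 21 published control-region subtypes.
# One representative taxon per subtype (taken from the published subtype
# membership lists) with the element/TR layout implied by the default rule
# table; the layouts are a documented reconstruction, not traced from the
# published schematic. n_species is the size of each subtype's membership
# list. The species D. chlorogaster is listed under two subtypes in the
# source; it is kept here as the IV-2 representative only.
subtype	general_type	taxon	n_species	tas1	tas2	csb1	csb2	csb3	order_ok	anormal	normal
I-1	I	Ac. aureus	4	1	1	1	1	1	1	-	-
I-2	I	Po. siculus	4	1	1	1	1	1	1	-	before_TAS1
I-3	I	Pe. laticeps	1	1	1	1	1	1	1	-	after_CSB3
I-4	I	E. stummeri	8	1	1	1	1	1	1	-	before_TAS1;after_CSB3
II-1	II	D. dahli	8	1	1	1	1	1	1	between_CSB1_CSB2	-
II-2	II	D. armeniaca	8	1	1	1	1	1	1	between_CSB1_CSB2	before_TAS1
II-3	II	E. scripta	1	1	1	1	1	1	1	between_CSB1_CSB2	before_TAS1;after_CSB3
III-1	III	T. septentrionalis	6	1	1	1	1	1	1	between_TAS2_CSB1	before_TAS1
IV-1	IV	E. brenchleyi	1	1	1	1	1	1	1	between_TAS1_TAS2	-
IV-2	IV	D. chlorogaster	1	1	1	1	1	1	1	between_TAS1_TAS2	before_TAS1
V-1	V	Al. nigropunctatus	1	0	0	0	1	1	1	-	-
V-2	V	Ac. guineensis	1	0	1	1	1	1	1	-	-
V-3	V	E. vermiculata	1	1	0	1	1	1	1	-	-
V-4	V	Ac. erythrurus	1	1	1	0	1	1	1	-	-
V-5	V	Au. australis	1	1	1	1	0	1	1	-	-
V-6	V	D. praticola	1	1	1	1	1	0	1	-	-
V-7	V	T. sexlineatus	1	0	0	1	1	1	1	-	-
V-8	V	T. amurensis	1	1	0	0	1	1	1	-	-
V-9	V	D. caucasica	1	1	1	0	0	1	1	-	-
V-10	V	D. clarkorum	1	1	1	1	0	0	1	-	-
V-11	V	Mer. squamulosus	1	1	1	1	1	1	0	-	-
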