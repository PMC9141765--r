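# Default control-region typing rules: five general types, 21 subtypes.
# The general types follow the published criteria (presence and position of
# TAS1, TAS2, CSB1, CSB2, CSB3 and of anormal tandem repeats located between
# the conserved elements); subtypes within a general type are distinguished
# by the placement of normal tandem repeats (before TAS1 / after CSB3).
# Because the published subtype layouts are defined only schematically, the
# concrete patterns below are a documented, editable reconstruction.
# Columns: tas1..csb3 presence (1 required present, 0 required absent,
# * any); order_ok (1/0/*); anormal and normal are ";"-separated required
# class sets ("-" = required empty, "*" = any); higher priority wins.
subtype	general_type	tas1	tas2	csb1	csb2	csb3	order_ok	anormal	normal	priority
I-1	I	1	1	1	1	1	1	-	-	100
I-2	I	1	1	1	1	1	1	-	before_TAS1	100
I-3	I	1	1	1	1	1	1	-	after_CSB3	100
I-4	I	1	1	1	1	1	1	-	before_TAS1;after_CSB3	100
II-1	II	1	1	1	1	1	1	between_CSB1_CSB2	-	100
II-2	II	1	1	1	1	1	1	between_CSB1_CSB2	before_TAS1	100
II-3	II	1	1	1	1	1	1	between_CSB1_CSB2	before_TAS1;after_CSB3	100
III-1	III	1	1	1	1	1	1	between_TAS2_CSB1	before_TAS1	100
IV-1	IV	1	1	1	1	1	1	between_TAS1_TAS2	-	100
IV-2	IV	1	1	1	1	1	1	between_TAS1_TAS2	before_TAS1	100
V-1	V	0	0	0	1	1	*	*	*	50
V-2	V	0	1	1	1	1	*	*	*	50
V-3	V	1	0	1	1	1	*	*	*	50
V-4	V	1	1	0	1	1	*	*	*	50
V-5	V	1	1	1	0	1	*	*	*	50
V-6	V	1	1	1	1	0	*	*	*	50
V-7	V	0	0	1	1	1	*	*	*	50
V-8	V	1	0	0	1	1	*	*	*	50
V-9	V	1	1	0	0	1	*	*	*	50
V-10	V	1	1	1	0	0	*	*	*	50
V-11	V	1	1	1	1	1	0	*	*	60
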