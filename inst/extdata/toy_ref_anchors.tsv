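gene_name	allele	segment_type	chain	anchor_codon_start	frame_offset
TRAV1	01	V	TRA	48	0
TRAV2	01	V	TRA	49	1
TRAV3-1	01	V	TRA	48	0
TRAV6	01	V	TRA	50	2
TRAV9	01	V	TRA	48	0
TRAV11	01	V	TRA	48	0
TRAV12D-1	01	V	TRA	48	0
TRAV13	01	V	TRA	49	1
TRAJ12	01	J	TRA	20	2
TRAJ18	01	J	TRA	35	2
TRAJ22	01	J	TRA	30	0
TRAJ26	01	J	TRA	22	1
TRAJ33	01	J	TRA	25	1
TRAJ40	01	J	TRA	23	2
TRBV1	01	V	TRB	48	0
TRBV2	01	V	TRB	49	1
TRBV12-1	01	V	TRB	48	0
TRBV13-1	01	V	TRB	50	2
TRBV16	01	V	TRB	48	0
TRBV19	01	V	TRB	48	0
TRBV26	01	V	TRB	49	1
TRBV31	01	V	TRB	48	0
TRBJ1-1	01	J	TRB	17	2
TRBJ1-4	01	J	TRB	19	1
TRBJ2-1	01	J	TRB	21	0
TRBJ2-3	01	J	TRB	20	2
TRBJ2-5	01	J	TRB	16	1
TRBJ2-7	01	J	TRB	17	2
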