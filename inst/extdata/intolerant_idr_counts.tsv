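gene	start	end	function_category	partner_category	transition_category	n_path_frameshift	n_pop_frameshift	n_path_nonsense	n_pop_nonsense	n_path_missense	n_pop_missense	n_path_inframe	n_pop_inframe
BMPR1A	24	54				5	0	1	0	0	12	2	0
BRCA2	21	39		Protein binding	Disorder to order	11	0	13	2	1	24	2	0
CDKN1B	1	198	Inhibitor	Protein binding		8	7	7	1	1	179	0	2
CDKN1B	25	90	Inhibitor	Protein binding	Disorder to order	4	2	5	0	1	52	0	1
CDKN1B	55	95		Protein binding		3	1	4	0	1	52	0	1
CDKN1C	27	97	Molecular recognition effector	Protein binding		2	0	1	4	0	68	0	0
CDKN2A	1	37				1	4	3	0	0	62	0	0
COL7A1	1940	1978				2	0	1	0	1	23	0	0
CSTB	1	67	Prion	Protein binding		1	1	3	1	3	46	0	1
DDX3X	1	167				7	0	6	0	5	0	0	0
EMD	1	187				11	0	10	0	5	76	2	3
EMD	67	170				4	0	4	0	0	50	2	1
KIT	544	565				1	0	3	1	21	7	14	0
LDLR	163	175	Flexible linker/spacer;Tethering			3	0	5	2	14	11	1	0
LDLR	354	393				13	1	10	2	37	33	4	0
MECP2	1	75	Molecular recognition assembler	Nucleic acid binding		21	0	10	0	2	26	0	1
MECP2	165	210	Assembler			13	0	13	0	2	46	1	1
MECP2	207	310	Inhibitor	Nucleic acid binding		77	0	13	0	14	60	4	0
MECP2	261	330				40	0	4	0	12	42	4	0
NFKBIA	1	66				0	0	4	1	7	31	0	2
PAX6	1	130			Disorder to order	18	3	12	0	23	69	0	0
RAF1	233	259				0	0	0	0	12	7	0	0
RB1	245	269				4	0	2	0	0	15	0	0
RB1	346	370	Flexible linker/spacer	Protein binding	Order to disorder	3	0	1	0	0	11	0	1
RB1	355	370				2	0	1	0	0	8	0	1
RB1	500	511				2	0	1	0	0	1	0	0
RB1	500	513				2	1	1	0	0	2	0	0
RB1	577	615	Flexible linker/spacer	Protein binding		2	0	4	0	0	22	0	0
RB1	786	928				6	0	12	0	1	65	0	1
SMAD4	297	306		Protein binding	Order to disorder	1	0	3	0	0	4	0	0
SUFU	279	360				2	1	1	0	0	58	0	0
TP53	60	92	Activator			17	0	4	0	0	36	0	2
TP53	291	312				8	4	4	0	2	26	1	0
WAS	201	268	Molecular recognition effector	Protein binding	Disorder to order	2	0	3	1	1	17	0	1
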