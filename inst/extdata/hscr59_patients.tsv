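sample_id	sex	hscr_form	syndromic	ret_status	haplotype
HSCR000	F	TCA	no	deletion	unknown
HSCR005	M	S	no	none	homozygous
HSCR018	M	L	no	mutation	no_risk
HSCR019	F	S	yes	none	homozygous
HSCR043	M	S	no	mutation	homozygous
HSCR045	M	L	no	none	rare
HSCR146	M	S	no	none	homozygous
HSCR195	M	S	no	mutation	homozygous
HSCR217	M	S	no	mutation	homozygous
HSCR403	F	S	no	none	homozygous
HSCR481	F	unknown	yes	none	unknown
HSCR006	M	L	no	none	homozygous
HSCR349	F	unknown	no	none	homozygous
HSCR374	F	L	no	none	homozygous
HSCRF01	M	L	yes	none	homozygous
HSCRF02	M	TCA	yes	none	homozygous
HSCRF03	M	L	yes	none	homozygous
HSCRF04	M	TCA	yes	mutation	homozygous
HSCRF05	M	L	yes	mutation	homozygous
HSCRF06	M	TCA	yes	mutation	homozygous
HSCRF07	M	L	yes	mutation	homozygous
HSCRF08	M	TCA	yes	mutation	homozygous
HSCRF09	M	L	no	mutation	homozygous
HSCRF10	M	TCA	no	mutation	homozygous
HSCRF11	M	L	no	mutation	homozygous
HSCRF12	M	TCA	no	mutation	homozygous
HSCRF13	M	L	no	none	homozygous
HSCRF14	M	TCA	no	none	homozygous
HSCRF15	M	L	no	none	homozygous
HSCRF16	M	TCA	no	none	homozygous
HSCRF17	M	S	no	none	homozygous
HSCRF18	M	S	no	none	homozygous
HSCRF19	M	S	no	none	homozygous
HSCRF20	M	S	no	none	homozygous
HSCRF21	M	S	no	none	homozygous
HSCRF22	M	S	no	none	homozygous
HSCRF23	M	S	no	none	homozygous
HSCRF24	M	S	no	none	homozygous
HSCRF25	M	S	no	none	homozygous
HSCRF26	M	S	no	none	homozygous
HSCRF27	M	S	no	none	homozygous
HSCRF28	M	S	no	none	homozygous
HSCRF29	M	S	no	none	homozygous
HSCRF30	M	S	no	none	homozygous
HSCRF31	M	S	no	none	homozygous
HSCRF32	M	S	no	none	homozygous
HSCRF33	M	S	no	none	homozygous
HSCRF34	M	S	no	none	homozygous
HSCRF35	F	S	no	none	homozygous
HSCRF36	F	S	no	none	homozygous
HSCRF37	F	S	no	none	heterozygous
HSCRF38	F	S	no	none	no_risk
HSCRF39	F	S	no	none	no_risk
HSCRF40	F	unknown	no	none	no_risk
HSCRF41	F	unknown	no	none	no_risk
HSCRF42	F	unknown	no	none	no_risk
HSCRF43	F	unknown	no	none	rare
HSCRF44	F	unknown	no	none	rare
HSCRF45	F	unknown	no	none	unknown
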