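variant_id	sample_id	chrom	start	end	type	n_probes	size	method	outcome	replicate_confirmed	dgv_freq	selected	parental_origin
1	HSCR000	chr9	110381888	110401999	gain	9	20111	qPCR	validated	TRUE	NA	TRUE	maternal
5	HSCR005	chr7	84217007	84225649	loss	4	8642	qPCR	validated	NA	0.008	TRUE	maternal
6	HSCR005	chr10	43679892	43680816	loss	5	924	PCR	failed	NA	NA	TRUE	NA
8	HSCR006	chr10	43679612	43680816	loss	6	1204	PCR	failed	NA	NA	TRUE	NA
20	HSCR018	chr9	109336464	109348467	gain	6	12003	qPCR	validated	NA	NA	TRUE	maternal
21	HSCR019	chr1	146638075	147824207	loss	4	2585968	qPCR	validated	TRUE	NA	TRUE	maternal
27	HSCR043	chr9	109273643	109275694	loss	2	2051	qPCR	validated	NA	NA	TRUE	maternal
28	HSCR045	chr7	84594683	84607065	loss	6	12382	qPCR	failed	NA	NA	TRUE	NA
29	HSCR045	chr8	32597644	32598929	loss	3	1285	qPCR	validated	NA	NA	TRUE	NA
30	HSCR045	chr10	43679612	43680816	loss	6	1204	PCR	failed	NA	NA	TRUE	NA
35	HSCR146	chr15	58257674	59009890	gain	2	752216	aCGH_8x60K	validated	NA	NA	TRUE	maternal
36	HSCR146	chr19	30888070	30891329	gain	2	3259	qPCR	failed	NA	NA	TRUE	NA
42	HSCR195	chr9	112078131	112089193	loss	5	11062	qPCR	not_conclusive	TRUE	NA	TRUE	NA
43	HSCR217	chr16	82200334	82202467	gain	2	2133	qPCR	validated	NA	NA	TRUE	de_novo
60	HSCR349	chr10	43573685	43574005	gain	2	320	qPCR	failed	NA	NA	TRUE	NA
61	HSCR374	chr10	43473690	43474033	gain	4	343	qPCR	failed	NA	NA	TRUE	NA
69	HSCR403	chr4	41746863	41751291	loss	11	4428	qPCR	validated	NA	NA	TRUE	maternal
82	HSCR481	chr19	31954093	31966036	loss	5	11943	qPCR	validated	NA	NA	TRUE	NA
72	HSCR403	chr22	21494163	21704972	gain	5	210809	none	not_attempted	TRUE	NA	FALSE	NA
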