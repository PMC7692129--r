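record_type	participant	sample_id	replicate	gene	chrom	pos	ref_nt	obs_nt	c_hgvs	transcript	p_hgvs	protein_ref	variant_type	interpretation	af	depth	valid	reason
variant	LAB01	EX-001	1	BRAF	chr7	140453136	A	T	c.1799T>A	NM_004333.4	p.(Val600Glu)	NP_004324.2	missense	pathogenic	13.1	1820	NA	NA
variant	LAB01	EX-001	2	BRAF	chr7	140453136	A	T	c.1799T>A	NM_004333.4	p.(Val600Glu)	NP_004324.2	missense	pathogenic	13.4	1764	NA	NA
variant	LAB01	EX-001	3	BRAF	chr7	140453136	A	T	c.1799T>A	NM_004333.4	p.(Val600Glu)	NP_004324.2	missense	pathogenic	12.9	1911	NA	NA
variant	LAB01	EX-001	1	KRAS	chr12	25378562	C	T	NA	NA	p.A146T	NA	missense	pathogenic	19.8	950	NA	NA
variant	LAB01	EX-001	2	KRAS	chr12	25378562	C	T	NA	NA	p.A146T	NA	missense	pathogenic	20.6	1003	NA	NA
variant	LAB01	EX-001	3	KRAS	chr12	25378562	C	T	NA	NA	p.A146T	NA	missense	pathogenic	20.2	987	NA	NA
variant	LAB02	EX-001	1	BRAF	chr7	140453136	A	T	NA	NA	p.Val600Glu	NA	missense	pathogenic	13.5	2100	NA	NA
variant	LAB02	EX-001	2	BRAF	chr7	140453136	A	T	NA	NA	p.Val600Glu	NA	missense	pathogenic	13.2	2043	NA	NA
variant	LAB02	EX-001	1	KRAS	chr12	25378562	C	T	NA	NA	p.Ala146Thr	NA	missense	pathogenic	21	1188	NA	NA
variant	LAB02	EX-001	2	KRAS	chr12	25378562	C	T	NA	NA	p.Ala146Thr	NA	missense	pathogenic	20.4	1090	NA	NA
variant	LAB02	EX-001	3	KRAS	chr12	25378562	C	T	NA	NA	p.Ala146Thr	NA	missense	pathogenic	20.9	1154	NA	NA
variant	LAB03	EX-001	1	BRAF	chr7	140453136	A	T	NA	NA	p(Val600Glu)	NA	missense	pathogenic	12.8	1575	NA	NA
variant	LAB03	EX-001	3	BRAF	chr7	140453136	A	T	NA	NA	p(Val600Glu)	NA	missense	pathogenic	13	1610	NA	NA
variant	LAB03	EX-001	1	KRAS	chr12	25378562	C	T	NA	NA	p.Ala146delinsThr	NA	missense	pathogenic	19.5	840	NA	NA
variant	LAB03	EX-001	3	KRAS	chr12	25378562	C	T	NA	NA	p.Ala146delinsThr	NA	missense	pathogenic	19.9	872	NA	NA
variant	LAB04	EX-001	1	BRAF	chr7	140453136	A	T	NA	NA	p.V600E	NA	missense	pathogenic	13.9	1330	NA	NA
variant	LAB04	EX-001	2	BRAF	chr7	140453136	A	T	NA	NA	p.V600E	NA	missense	pathogenic	13.7	1295	NA	NA
variant	LAB04	EX-001	3	BRAF	chr7	140453136	A	T	NA	NA	p.V600E	NA	missense	pathogenic	14.1	1402	NA	NA
variant	LAB05	EX-001	1	BRAF	chr7	140453136	A	T	NA	NA	p.(Val600Glu)	NA	missense	pathogenic	12.6	990	NA	NA
variant	LAB05	EX-001	2	BRAF	chr7	140453136	A	T	NA	NA	p.(Val600Glu)	NA	missense	pathogenic	13	1012	NA	NA
variant	LAB05	EX-001	3	BRAF	chr7	140453136	A	T	NA	NA	p.(Val600Glu)	NA	missense	pathogenic	13.3	975	NA	NA
variant	LAB05	EX-001	1	KRAS	chr12	25378562	C	T	NA	NA	p.(Ala146Thr)	NA	missense	pathogenic	20	1230	NA	NA
variant	LAB05	EX-001	2	KRAS	chr12	25378562	C	T	NA	NA	p.(Ala146Thr)	NA	missense	pathogenic	19.7	1260	NA	NA
variant	LAB05	EX-001	3	KRAS	chr12	25378562	C	T	NA	NA	p.(Ala146Thr)	NA	missense	pathogenic	20.3	1244	NA	NA
variant	LAB06	EX-001	1	BRAF	chr7	140453136	A	T	NA	NA	p.(Val600Glu)	NA	missense	pathogenic	13.2	1500	NA	NA
variant	LAB06	EX-001	2	BRAF	chr7	140453136	A	T	NA	NA	p.(Val600Glu)	NA	missense	pathogenic	13.1	1490	NA	NA
variant	LAB06	EX-001	3	BRAF	chr7	140453136	A	T	NA	NA	p.(Val600Glu)	NA	missense	pathogenic	13.4	1505	NA	NA
variant	LAB06	EX-001	1	KRAS	chr12	25378562	C	T	NA	NA	p.(Ala146Thr)	NA	missense	pathogenic	20.8	1110	NA	NA
variant	LAB06	EX-001	2	KRAS	chr12	25378562	C	T	NA	NA	p.(Ala146Thr)	NA	missense	pathogenic	20.5	1098	NA	NA
variant	LAB06	EX-001	3	KRAS	chr12	25378562	C	T	NA	NA	p.(Ala146Thr)	NA	missense	pathogenic	21.1	1120	NA	NA
status	LAB03	EX-001	2	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	sequencing failed routine QC
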