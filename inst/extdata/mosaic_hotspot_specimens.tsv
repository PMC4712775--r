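patient_id	specimen_id	tissue	role	organ	purity	assay	chgvs	phgvs	var_reads	total_reads	vaf_pct	detected	allele_loss	cnv	source
101	101-blood	Blood	blood	blood	NA	sanger	c.5126A>G	p.D1709G	NA	NA	NA	1	0		this_study
101	101-ln	Normal lymph node	normal_tissue	lymph_node	NA	ngs	c.5126A>G	p.D1709G	10	66	15.2	NA	0		this_study
102	102-blood	Blood	blood	blood	NA	ngs	c.5125G>A	p.D1709N	22	477	4.61	NA	0		this_study
102	102-brain	Brain, PPB metastasis	tumor	brain	0.30	ngs	c.5125G>A	p.D1709N	213	418	51.0	NA	1		this_study
103	103-blood	Blood	blood	blood	NA	ngs	c.5125G>A	p.D1709N	18	6413	0.28	NA	0		this_study
103	103-kid	Kidney, CN	tumor	kidney	0.40	ngs	c.5125G>A	p.D1709N	174	1172	14.9	NA	0		this_study
103	103-kid	Kidney, CN	tumor	kidney	0.40	ngs	c.1129G>A	p.V377I	5	159	3.1	NA	0		this_study
103	103-lung	Lung, PPB Type IR	tumor	lung	0.20	ngs	c.5125G>A	p.D1709N	30	185	16.2	NA	0		this_study
103	103-lung	Lung, PPB Type IR	tumor	lung	0.20	ngs	c.1200G>A	p.W400*	11	141	4.1	NA	0		this_study
103	103-si	Small intestine, polyp	tumor	small_intestine	0.25	ngs	c.5125G>A	p.D1709N	65	371	17.5	NA	0		this_study
103	103-si	Small intestine, polyp	tumor	small_intestine	0.25	ngs	c.96G>A	p.W32*	13	431	3.0	NA	0		this_study
104	104-blood	Blood	blood	blood	NA	ngs	c.5428G>T	p.D1810Y	13	6217	0.21	NA	0		this_study
104	104-ft	Normal fallopian tube	normal_tissue	fallopian_tube	NA	ngs	c.5428G>T	p.D1810Y	141	1961	7.19	NA	0		this_study
104	104-lung	Lung, PPB Type IR	tumor	lung	0.20	ngs	c.5428G>T	p.D1810Y	193	694	27.8	NA	0		this_study
104	104-kid	Kidney, CN	tumor	kidney	0.20	ngs	c.5428G>T	p.D1810Y	64	219	29.2	NA	0		this_study
104	104-kid	Kidney, CN	tumor	kidney	0.20	ngs	c.1711delT	p.S571Vfs*16	73	192	21.8	NA	0		this_study
104	104-ovr	Ovary (right), SLCT	tumor	ovary_right	0.34	ngs	c.5428G>T	p.D1810Y	684	1988	34.2	NA	0		this_study
104	104-ovr	Ovary (right), SLCT	tumor	ovary_right	0.34	ngs	c.1775delA	p.K592Mfs*15	721	1993	36.2	NA	0		this_study
104	104-ovl	Ovary (left), SLCT	tumor	ovary_left	0.95	ngs	c.5428G>T	p.D1810Y	1837	1988	92.4	NA	1		this_study
105	105-blood	Blood	blood	blood	NA	ngs	c.5437G>C	p.E1813Q	1	2450	0.04	NA	0		this_study
105	105-nas	Nasal cavity, NCMH	tumor	nasal_cavity	0.20	ngs	c.5437G>C	p.E1813Q	579	1977	29.3	NA	0		this_study
105	105-thy	Thyroid, follicular Ca	tumor	thyroid	0.60	ngs	c.5437G>C	p.E1813Q	289	434	66.6	NA	1		this_study
105	105-ovr	Ovary (right), SLCT	tumor	ovary_right	0.75	ngs	c.5437G>C	p.E1813Q	750	976	76.8	NA	1		this_study
105	105-ovl	Ovary (left), SLCT	tumor	ovary_left	0.25	ngs	c.5437G>C	p.E1813Q	624	1962	31.8	NA	0		this_study
105	105-ovl	Ovary (left), SLCT	tumor	ovary_left	0.25	ngs	c.4626delC	p.Q1542Hfs*18	430	1984	21.7	NA	0		this_study
120	120-blood	Blood	blood	blood	NA	ngs	c.5425G>A	p.G1809R	NA	NA	NA	0	0		this_study
120	120-rlung	Reactive lung	normal_tissue	lung	NA	ngs	c.5425G>A	p.G1809R	36	3442	1.0	NA	0		this_study
120	120-lung	Lung, PPB type II	tumor	lung	NA	ngs	c.5425G>A	p.G1809R	1455	3972	37	NA	0		this_study
120	120-lung	Lung, PPB type II	tumor	lung	NA	ngs	c.1966C>T	p.R656*	NA	NA	NA	1	0		this_study
123	123-blood	Blood	blood	blood	NA	ngs	c.5113G>A	p.E1705K	NA	NA	NA	0	0		this_study
123	123-ur	Normal ureter	normal_tissue	ureter	NA	ngs	c.5113G>A	p.E1705K	19	148	13	NA	0		this_study
123	123-lung	Lung, PPB type I	tumor	lung	0.20	ngs	c.5113G>A	p.E1705K	46	192	24	NA	1		this_study
123	123-kid	Kidney, CN	tumor	kidney	0.25	ngs	c.5113G>A	p.E1705K	33	94	35	NA	1		this_study
klein_1	k1-blood	Blood	blood	blood	NA	ngs	c.5138A>T	p.D1713V	NA	NA	21	1	0		klein_case_1
klein_1	k1-kid	Normal kidney	normal_tissue	kidney	NA	ngs	c.5138A>T	p.D1713V	NA	NA	35	1	0		klein_case_1
klein_1	k1-wilms	Wilms tumor	tumor	kidney	NA	ngs	c.5138A>T	p.D1713V	NA	NA	37	1	0		klein_case_1
klein_1	k1-wilms	Wilms tumor	tumor	kidney	NA	ngs	c.1304C>T	p.P453L	NA	NA	NA	1	0		klein_case_1
klein_2	k2-blood	Blood	blood	blood	NA	ngs	c.5125G>T	p.D1709Y	NA	NA	28	1	0		klein_case_2
klein_2	k2-kid	Normal kidney	normal_tissue	kidney	NA	ngs	c.5125G>T	p.D1709Y	NA	NA	35	1	0		klein_case_2
klein_2	k2-wilms	Wilms tumor	tumor	kidney	NA	ngs	c.5125G>T	p.D1709Y	NA	NA	47	1	0		klein_case_2
dekock_12	dk-blood	Blood	blood	blood	NA	sanger	c.5125G>C	p.D1709H	NA	NA	NA	1	0		dekock_case_12
dekock_12	dk-pit	Pituitary blastoma	tumor	pituitary	NA	sanger	c.5125G>C	p.D1709H	NA	NA	NA	1	1		dekock_case_12
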