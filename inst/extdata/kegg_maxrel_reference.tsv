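rank	term_id	name	mi
1	hsa04080	Neuroactive ligand-receptor interaction	0.026
2	hsa00400	Phenylalanine, tyrosine and tryptophan biosynthesis	0.024
3	hsa05322	Systemic lupus erythematosus	0.02
4	hsa04726	Serotonergic synapse	0.018
5	hsa00591	Linoleic acid metabolism	0.017
6	hsa05213	Endometrial cancer	0.016
7	hsa00531	Glycosaminoglycan degradation	0.016
8	hsa04146	Peroxisome	0.016
9	hsa00100	Steroid biosynthesis	0.015
10	hsa00603	Glycosphingolipid biosynthesis—globo serie	0.015
11	hsa04530	Tight junction	0.014
12	hsa04666	Fc gamma R-mediated phagocytosis	0.014
13	hsa00130	Ubiquinone and other terpenoid-quinone biosynthesis	0.013
14	hsa04610	Complement and coagulation cascades	0.013
15	hsa00240	Pyrimidine metabolism	0.013
16	hsa04020	Calcium signaling pathway	0.013
17	hsa04725	Cholinergic synapse	0.013
18	hsa00280	Valine, leucine and isoleucine degradation	0.013
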