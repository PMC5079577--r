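rank	term_id	name	mi
1	GO:0015347	sodium-independent organic anion transmembrane transporter activity	0.037
2	GO:0060033	anatomical structure regression	0.036
3	GO:0050998	nitric-oxide synthase binding	0.036
4	GO:0035115	embryonic forelimb morphogenesis	0.035
5	GO:0046972	histone acetyltransferase activity (H4-K16 specific)	0.034
6	GO:0043995	histone acetyltransferase activity (H4-K5 specific)	0.034
7	GO:0043996	histone acetyltransferase activity (H4-K8 specific)	0.034
8	GO:0050805	negative regulation of synaptic transmission	0.034
9	GO:0042364	water-soluble vitamin biosynthetic process	0.032
10	GO:0001533	cornified envelope	0.031
11	GO:0008504	monoamine transmembrane transporter activity	0.031
12	GO:0021853	cerebral cortex GABAergic interneuron migration	0.031
13	GO:0021830	interneuron migration from the subpallium to the cortex	0.031
14	GO:0021894	cerebral cortex GABAergic interneuron development	0.031
15	GO:0021534	cell proliferation in hindbrain	0.031
16	GO:0001965	G-protein alpha-subunit binding	0.03
17	GO:1901386	negative regulation of voltage-gated calcium channel activity	0.03
18	GO:0021924	cell proliferation in external granule layer	0.03
19	GO:0021930	cerebellar granule cell precursor proliferation	0.03
20	GO:0046341	CDP-diacylglycerol metabolic process	0.03
21	GO:0019992	diacylglycerol binding	0.03
22	GO:0003881	CDP-diacylglycerol-inositol 3-phosphatidyltransferase activity	0.03
23	GO:0090177	establishment of planar polarity involved in neural tube closure	0.03
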