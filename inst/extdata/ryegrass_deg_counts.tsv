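tissue	scheme	contrast	j1	j3	deseq2	edger	limma_voom
leaf	AR/TC	Early	1050	642	934	754	774
leaf	AR	Middle	1838	1195	1564	1450	1494
leaf	TC	Middle	1860	1290	1622	1502	1553
leaf	AR	Late	3762	3024	3311	3352	3497
leaf	TC	Late	2701	2065	2397	2334	2403
root	AR/TC	Early	5	0	5	0	0
root	AR	Middle	844	0	844	0	1
root	TC	Middle	186	1	186	4	1
root	AR	Late	3932	2903	3673	3344	3380
root	TC	Late	2757	1787	2622	2196	2189
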