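chrom	numts_count	chrom_length	total_span	span_percent
1	46	247249719	57670	0.023
2	92	242951149	108317	0.045
3	39	199501827	24203	0.012
4	38	191273063	36179	0.019
5	24	180857866	40163	0.022
6	31	170899992	11708	0.007
7	35	158821424	51356	0.032
8	37	146274826	46805	0.032
9	28	140273252	36854	0.026
10	33	135374737	21445	0.016
11	28	134452384	26640	0.020
12	40	132349534	8551	0.006
13	19	114142980	11159	0.010
14	8	106368585	8991	0.008
15	12	100338915	9002	0.009
16	11	88827254	17205	0.019
17	17	78774742	24285	0.031
18	7	76117153	1340	0.002
19	15	63811651	19373	0.030
20	10	62435964	5905	0.009
21	8	46944323	7210	0.015
22	8	49691432	9025	0.018
X	13	154913754	30845	0.020
Y	12	57772954	11510	0.020
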