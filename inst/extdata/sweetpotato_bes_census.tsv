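class_path	n_elements	masked_bp	pct_of_total
Class I retrotransposon	2414	646519	8.51
Class I retrotransposon|LTR retrotransposons	1984	559396	7.37
Class I retrotransposon|LTR retrotransposons|Ty1/copia	873	276307	3.64
Class I retrotransposon|LTR retrotransposons|Gypsy/DIRS	1008	274869	3.62
Class I retrotransposon|LTR retrotransposons|Others	103	8220	0.11
Class I retrotransposon|Non-LTR retrotransposons	430	87123	1.15
Class I retrotransposon|Non-LTR retrotransposons|SINE	15	1018	0.01
Class I retrotransposon|Non-LTR retrotransposons|LINE	415	86105	1.13
Class II DNA transposons	673	107599	1.42
Class II DNA transposons|hobo-Activator	168	26272	0.35
Class II DNA transposons|TcMar	26	2226	0.03
Class II DNA transposons|CMC-EnSpm	133	19577	0.26
Class II DNA transposons|MULE-MuDR	116	20521	0.27
Class II DNA transposons|RC/Helitron	102	29024	0.38
Class II DNA transposons|PiggyBac	1	85	0.00
Class II DNA transposons|Tourist/Harbinger	24	2340	0.03
Class II DNA transposons|Others	103	7554	0.10
Unclassified	11	752	0.01
Total interspersed repeats	3098	754870	9.94
Small RNA	34	4925	0.06
Satellites	26	2954	0.04
Simple repeats	3408	147232	1.94
Low complexity	550	26125	0.34
Total repetitive DNA	7116	924646	12.17
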