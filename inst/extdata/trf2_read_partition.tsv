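chrom	subtelomeric	interstitial
chr1	2933	236762.5
chr2	1366.5	235044
chr3	1761	189761
chr4	2721.5	179752
chr5	4848	175975
chr6	1172	155155.5
chr7	1469.5	170633.5
chr8	1312	138489
chr9	1915	128188.5
chr10	2007.5	147970
chr11	1756.5	132698
chr12	2612.5	135934
chr13	365.5	86333
chr14	367.5	87953.5
chr15	1054.5	82229
chr16	1628	96387.5
chr17	1093	91077.5
chr18	3326	67039.5
chr19	982.5	78062
chr20	1759	59221.5
chr21	715	40403.5
chr22	560	39900.5
chrX	2441	151597.5
chrY	10821.5	44276.5
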