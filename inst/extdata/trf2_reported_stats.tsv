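metric	value
total_reads	26400000
aligned_reads	15800000
telomeric_reads	3600000
reads_in_peaks_rep1	2999796
reads_in_peaks_rep2	3041641
peaks_rep1	31424
peaks_rep2	30433
common_peaks	20304
high_confidence_peaks	1956
tss_within_20kb	7056
tss_within_10kb	3635
tss_within_5kb	1984
ttaggg_containing_hc_peaks	465
enriched_bin_percent	2.79
printed_aligned_percent	60
printed_telomeric_percent	23
printed_reads_in_peaks_rep1_percent	18.9
printed_reads_in_peaks_rep2_percent	19.1
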