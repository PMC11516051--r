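gene_id	chrom	strand	start	end	cds_start	proximal_pas	distal_pas	pal_diff	apa_shift	delta_red_true	pal_median_callus	pal_median_xylem	usage_proximal_callus	usage_proximal_xylem
g0001	chr1	+	1	2800	151	2640	2760	FALSE	FALSE	0	177.147368458376	177.147368458376	0.5	0.5
g0002	chr2	-	1	2800	2650	161	41	FALSE	FALSE	0	74.141636118066	74.141636118066	0.5	0.5
g0003	chr1	+	4801	7600	4951	7440	7560	FALSE	FALSE	0	84.065567377476	84.065567377476	0.5	0.5
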