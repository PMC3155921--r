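# Published mutation-spectrum counts for budding yeast, entered from the
# primary literature for side-by-side comparison with centromere spectra.
# ts/tv: transition and transversion base-pair substitution counts.
# one_bp_deletions / one_bp_insertions: single-base indels outside
# homopolymer runs of >= 5 bp; other: multi-base indels plus in-run indels.
# wild_type marks spontaneous wild-type baselines; the gene-conversion assay
# row (ura3_hicks_gc) is the contrast; cdeii_centromeres holds the polarized
# counts from centromere CDEII resequencing.
study	wild_type	ts	tv	one_bp_deletions	one_bp_insertions	other
cdeii_centromeres	FALSE	46	68	4	0	18
genomewide_wt	TRUE	12	19	1	0	1
ura3_lang_wt	TRUE	46	121	22	3	15
can1_lang_wt	TRUE	65	85	56	8	13
ura3_hicks_wt	TRUE	19	27	5	1	9
ura3_hicks_gc	FALSE	32	24	32	1	14
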