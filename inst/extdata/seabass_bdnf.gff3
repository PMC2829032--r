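##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-24
seabass_bdnf_locus	rtracklayer	gene	321	15130	.	+	.	Name=BDNF;
seabass_bdnf_locus	rtracklayer	exon	321	602	.	+	.	Name=1beta;is_coding=false
seabass_bdnf_locus	rtracklayer	exon	1367	1818	.	+	.	Name=1a;is_coding=false
seabass_bdnf_locus	rtracklayer	exon	4270	4315	.	+	.	Name=1b;is_coding=false
seabass_bdnf_locus	rtracklayer	exon	8347	8646	.	+	.	Name=1c;is_coding=false
seabass_bdnf_locus	rtracklayer	exon	11540	11797	.	+	.	Name=1d;is_coding=false
seabass_bdnf_locus	rtracklayer	exon	14063	15130	.	+	.	Name=2;is_coding=true
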