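##fileformat=VCFv4.2
##synthetic toy fixture: 12 candidate RNA variants; records 1-5 pass all
##post-caller filters (record 3 sits exactly on the 1% VAF boundary, which
##passes); records 6-12 each violate exactly one rule, named in ID.
##INFO=<ID=RNAD,Number=1,Type=Integer,Description="RNA depth">
##INFO=<ID=RNAA,Number=1,Type=Integer,Description="RNA alt reads">
##INFO=<ID=DPG,Number=1,Type=Integer,Description="Germline DNA depth">
##INFO=<ID=DPT,Number=1,Type=Integer,Description="Total tumour DNA depth">
##INFO=<ID=ALTS,Number=1,Type=Integer,Description="Tumour DNA alt support">
##INFO=<ID=ERRS,Number=1,Type=Integer,Description="Tumour DNA other non-reference support">
##INFO=<ID=C5,Number=1,Type=String,Description="4-base 5-prime genomic flank">
##INFO=<ID=C3,Number=1,Type=String,Description="4-base 3-prime genomic flank">
##INFO=<ID=STR,Number=1,Type=String,Description="Transcript strand">
##INFO=<ID=TID,Number=1,Type=String,Description="Tumour id">
##INFO=<ID=RID,Number=1,Type=String,Description="Region id">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
TX001	101	pass_1	A	G	.	.	RNAD=50;RNAA=15;DPG=60;DPT=120;ALTS=0;ERRS=0;C5=GCTA;C3=TACG;STR=+;TID=T01;RID=T01_R1
TX001	250	pass_2	C	T	.	.	RNAD=80;RNAA=24;DPG=45;DPT=90;ALTS=0;ERRS=1;C5=ATGC;C3=CGAT;STR=+;TID=T01;RID=T01_R1
TX001	399	pass_vaf_boundary	C	T	.	.	RNAD=300;RNAA=3;DPG=50;DPT=100;ALTS=0;ERRS=0;C5=TTGA;C3=ACCA;STR=+;TID=T01;RID=T01_R1
TX002	120	pass_4	T	C	.	.	RNAD=40;RNAA=12;DPG=70;DPT=140;ALTS=0;ERRS=0;C5=CAGT;C3=GTCA;STR=-;TID=T01;RID=T01_R1
TX002	305	pass_5	G	A	.	.	RNAD=65;RNAA=20;DPG=55;DPT=110;ALTS=1;ERRS=2;C5=ACTG;C3=TGAC;STR=-;TID=T01;RID=T01_R1
TX001	520	fail_low_germline	A	G	.	.	RNAD=50;RNAA=15;DPG=20;DPT=120;ALTS=0;ERRS=0;C5=GCTA;C3=TACG;STR=+;TID=T01;RID=T01_R1
TX001	640	fail_low_tumour_depth	C	T	.	.	RNAD=50;RNAA=15;DPG=60;DPT=25;ALTS=0;ERRS=0;C5=ATGC;C3=CGAT;STR=+;TID=T01;RID=T01_R1
TX001	760	fail_low_rna_coverage	C	T	.	.	RNAD=9;RNAA=3;DPG=60;DPT=120;ALTS=0;ERRS=0;C5=TTGA;C3=ACCA;STR=+;TID=T01;RID=T01_R1
TX002	430	fail_low_alt_support	T	C	.	.	RNAD=50;RNAA=2;DPG=60;DPT=120;ALTS=0;ERRS=0;C5=CAGT;C3=GTCA;STR=-;TID=T01;RID=T01_R1
TX002	550	fail_low_vaf	G	A	.	.	RNAD=1000;RNAA=5;DPG=60;DPT=120;ALTS=0;ERRS=0;C5=ACTG;C3=TGAC;STR=-;TID=T01;RID=T01_R1
TX002	670	fail_dna_support	C	T	.	.	RNAD=50;RNAA=15;DPG=60;DPT=600;ALTS=12;ERRS=0;C5=GATC;C3=CTAG;STR=-;TID=T01;RID=T01_R1
TX001	880	fail_homopolymer	A	G	.	.	RNAD=50;RNAA=15;DPG=60;DPT=120;ALTS=0;ERRS=0;C5=AAAA;C3=TACG;STR=+;TID=T01;RID=T01_R1
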