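gene_id	ensembl_id	hr_grade_1	hr_grade_2	gfp_grade	viability_grade	cisplatin	mmc	ir	h2ax
ACTB	ENSG00000075624	↓	↓↓	-	-	-	-	-	-
AIP	ENSG00000110711	↓	↓↓	-	-	-	++	-	-
ALOX15	ENSG00000161905	↓↓	↓↓	-	+	-	++	-	-
ARHGEF1	ENSG00000076928	↓↓	↓↓	-	+	-	+	-	↓ 1h, ↓ 6h
BCAM	ENSG00000187244	↓↓	↓↓	-	+	-	+	-	-
BRCA1	ENSG00000012048	↓↓↓	↓↓↓	-	+	+	+++	+	↑ 6h
C1orf63	ENSG00000117616	↓↓	↓↓	-	-	+	+	+	↑ 6h
CHCHD2	ENSG00000106153	↓↓	↓↓	-	+	-	++	-	-
DRG2	ENSG00000108591	↓↓	↓↓	-	-	-	+++	-	-
ETFB	ENSG00000105379	↓↓	↓↓	-	+	-	++	-	-
FAM110C	ENSG00000184731	↓↓	↓	-	+	-	-	-	-
FIZ1	ENSG00000179943	↓↓	↓	-	-	-	+	-	↓ 6h
GAK	ENSG00000178950	↓↓	↓↓	-	-	-	+	-	-
HNRPA0	ENSG00000177733	↓↓	↓↓	-	-	-	+	-	↓ 6h
IGLON5	ENSG00000142549	↓↓	↓↓	-	-	-	+	-	-
KIAA0415	ENSG00000164917	↓↓	↓↓	-	-	-	++	-	-
NTHL1	ENSG00000065057	↓↓	↓↓	-	-	-	+++	-	↑ 6h
OSBPL5	ENSG00000021762	↓	↓↓	-	-	+	-	++	-
PRPF40B	ENSG00000110844	↓↓	↓↓	-	-	-	++	-	↑ 6h
PSMD4	ENSG00000159352	↓↓	↓↓↓	-	+	-	+	-	-
RAD51	ENSG00000051180	↓↓↓	↓↓↓	-	+	+++	+++	++	↑ 6h
RBBP8	ENSG00000101773	↓↓	↓↓	-	-	-	++	+	↑ 6h
RBM42	ENSG00000126254	↓↓	↓↓	-	-	-	++	-	-
RECQL4	ENSG00000160957	↓↓	↓	-	-	-	++	+	-
SEMA7A	ENSG00000138623	↓↓	↓↓	-	+	-	-	-	-
SERPINH1	ENSG00000149257	↓↓	↓	-	+	-	-	-	-
SHFM1	ENSG00000127922	↓↓↓	n.a.	-	-	++	+++	-	-
TRMT2A	ENSG00000099899	↓↓	↓	-	+	+	-	-	↑ 6h
TSKU	ENSG00000182704	↓	↓↓	-	-	-	+	-	-
XPC	ENSG00000154767	↓↓	↓↓	-	+	-	++	-	-
ZMYND15	ENSG00000141497	↓	↓↓	-	-	-	+++	-	-
ARCN1	ENSG00000095139	↓	↓↓	-	++	n.d.	n.d.	n.d.	n.d.
CKAP5	ENSG00000175216	↓↓	↓↓	-	++	n.d.	n.d.	n.d.	n.d.
CWC22	ENSG00000163510	↓↓↓	↓↓	-	++	n.d.	n.d.	n.d.	n.d.
DDB1	ENSG00000167986	↓↓	↓↓	-	++	n.d.	n.d.	n.d.	n.d.
E2F1	ENSG00000101412	↓	↓↓	-	++	n.d.	n.d.	n.d.	n.d.
HNRPK	ENSG00000165119	↓↓	↓↓	-	++	n.d.	n.d.	n.d.	n.d.
PSMD1	ENSG00000173692	↓↓↓	↓↓↓	-	++	n.d.	n.d.	n.d.	n.d.
PSMD14	ENSG00000115233	↓↓	↓↓↓	-	++	n.d.	n.d.	n.d.	n.d.
SNRNP200	ENSG00000144028	↓↓	↓↓↓	-	++	n.d.	n.d.	n.d.	n.d.
THOC4	ENSG00000183684	↓↓	↓↓	-	++	n.d.	n.d.	n.d.	n.d.
TPX2	ENSG00000088325	↓↓	↓↓↓	-	++	n.d.	n.d.	n.d.	n.d.
VPRBP	ENSG00000145041	↓↓↓	↓↓	-	++	n.d.	n.d.	n.d.	n.d.
ZYG11BL	ENSG00000160445	↓	↓↓	-	++	n.d.	n.d.	n.d.	n.d.
MKNK2	ENSG00000099875	↓↓	↓↓	+	-	n.d.	n.d.	n.d.	n.d.
ATXN3	ENSG00000066427	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
C5orf28	ENSG00000151881	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
C6	ENSG00000039537	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
CNGA1	ENSG00000198515	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
CREBBP	ENSG00000005339	↑	↑↑↑	-	-	n.d.	n.d.	n.d.	n.d.
DNAJB4	ENSG00000162616	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
LIG4	ENSG00000174405	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
LYRM7	ENSG00000186687	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
MMRN1	ENSG00000138722	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
PDHX	ENSG00000110435	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
SLC39A12	ENSG00000148482	↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
SMCHD1	ENSG00000101596	↑↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
SMS	ENSG00000102172	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
STAG2	ENSG00000101972	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
USP12	ENSG00000152484	↑↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
WRB	ENSG00000182093	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
XRCC2	ENSG00000196584	↑↑	↑↑	-	-	n.d.	n.d.	n.d.	n.d.
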