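# Canonical universal 16S rRNA gene primers (IUPAC degeneracy codes).
# Edit or replace this file to supply your own primer set; the package
# never hardcodes primer sequences.
name	sequence	orientation
27F	AGAGTTTGATCMTGGCTCAG	forward
338R	TGCTGCCTCCCGTAGGAGT	reverse
515F	GTGYCAGCMGCCGCGGTAA	forward
806R	GGACTACNVGGGTWTCTAAT	reverse
799F	AACMGGATTAGATACCCKG	forward
1193R	ACGTCATCCCCACCTTCC	reverse
1114F	GCAACGAGCGCAACCC	forward
1392R	ACGGGCGGTGTGTRC	reverse
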