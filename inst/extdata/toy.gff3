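##gff-version 3
# sequence-region toy 1 120 circular
toy	orthopair	CDS	1	9	.	+	0	ID=TOY_0001;locus_tag=TOY_0001;product=toy protein
toy	orthopair	tRNA	21	96	.	-	.	ID=TOY_t001;locus_tag=TOY_t001;product=tRNA-Xxx
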