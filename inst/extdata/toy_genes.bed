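chrA	9999	20500	GENEA	0	+	9999	20500	0	3	501,501,501	0,4000,10000
chrB	49999	64500	GENEB	0	-	49999	64500	0	3	501,501,501	0,7000,14000
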