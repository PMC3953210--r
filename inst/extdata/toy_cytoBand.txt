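chr2	0	10000000	p25.1	gneg
chr2	10000000	30000000	p24.1	gpos50
chr2	30000000	92000000	p11.2	gneg
chr2	92000000	100000000	q11.1	acen
chr2	100000000	165000000	q24.2	gpos75
chr2	165000000	190000000	q32.1	gneg
chr2	190000000	200000000	q33	gpos25
chr7	0	60000000	p11.1	gneg
chr7	60000000	130000000	q32	gpos50
chr7	130000000	160000000	q33	gneg
chr19	0	50000000	p13.1	gneg
chr19	50000000	59000000	q13.4	gpos25
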