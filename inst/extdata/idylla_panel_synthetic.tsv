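gene	cdna	protein	vendor_label	class	cartridge
BRAF	c.1799T>A	p.V600E	V600E	snv	BRAF
BRAF	c.1799_1800delinsAC	p.V600D	V600D	indel	BRAF
BRAF	c.1798_1799delinsAA	p.V600K	V600K	indel	BRAF
BRAF	c.1798_1799delinsAG	p.V600R	V600R	indel	BRAF
BRAF	c.1798G>A	p.V600M	V600M	snv	BRAF
NRAS	c.34G>A	p.G12S	G12S	snv	NRAS/BRAF
NRAS	c.34G>T	p.G12C	G12C	snv	NRAS/BRAF
NRAS	c.35G>C	p.G12A	G12A	snv	NRAS/BRAF
NRAS	c.35G>A	p.G12D	G12D	snv	NRAS/BRAF
NRAS	c.35G>T	p.G12V	G12V	snv	NRAS/BRAF
NRAS	c.37G>C	p.G13R	G13R	snv	NRAS/BRAF
NRAS	c.38G>A	p.G13D	G13D	snv	NRAS/BRAF
NRAS	c.38G>T	p.G13V	G13V	snv	NRAS/BRAF
NRAS	c.173C>T	p.T58I	T58I	snv	NRAS/BRAF
NRAS	c.175G>A	p.A59T	A59T	snv	NRAS/BRAF
NRAS	c.176C>A	p.A59D	A59D	snv	NRAS/BRAF
NRAS	c.181C>A	p.Q61K	Q61K	snv	NRAS/BRAF
NRAS	c.182A>T	p.Q61L	Q61L	snv	NRAS/BRAF
NRAS	c.182A>G	p.Q61R	Q61R	snv	NRAS/BRAF
NRAS	c.183A>T	p.Q61H	Q61H	snv	NRAS/BRAF
NRAS	c.351G>C	p.K117N	K117N	snv	NRAS/BRAF
NRAS	c.436G>A	p.A146T	A146T	snv	NRAS/BRAF
NRAS	c.437C>T	p.A146V	A146V	snv	NRAS/BRAF
KRAS	c.34G>A	p.G12S	G12S	snv	KRAS
KRAS	c.34G>T	p.G12C	G12C	snv	KRAS
KRAS	c.34G>C	p.G12R	G12R	snv	KRAS
KRAS	c.35G>C	p.G12A	G12A	snv	KRAS
KRAS	c.35G>A	p.G12D	G12D	snv	KRAS
KRAS	c.35G>T	p.G12V	G12V	snv	KRAS
KRAS	c.38G>A	p.G13D	G13D	snv	KRAS
KRAS	c.175G>A	p.A59T	A59T	snv	KRAS
KRAS	c.176C>A	p.A59E	A59E	snv	KRAS
KRAS	c.176C>G	p.A59G	A59G	snv	KRAS
KRAS	c.183A>C	p.Q61H	Q61H	snv	KRAS
KRAS	c.181C>A	p.Q61K	Q61K	snv	KRAS
KRAS	c.182A>T	p.Q61L	Q61L	snv	KRAS
KRAS	c.182A>G	p.Q61R	Q61R	snv	KRAS
KRAS	c.351A>C	p.K117N	K117N	snv	KRAS
KRAS	c.436G>C	p.A146P	A146P	snv	KRAS
KRAS	c.436G>A	p.A146T	A146T	snv	KRAS
KRAS	c.437C>T	p.A146V	A146V	snv	KRAS
EGFR	c.2155G>A	p.G719S	G719	snv	EGFR
EGFR	c.2155G>T	p.G719C	G719	snv	EGFR
EGFR	c.2156G>C	p.G719A	G719	snv	EGFR
EGFR	c.2303G>T	p.S768I	S768I	snv	EGFR
EGFR	c.2369C>T	p.T790M	T790M	snv	EGFR
EGFR	c.2573T>G	p.L858R	L858R	snv	EGFR
EGFR	c.2582T>A	p.L861Q	L861Q	snv	EGFR
EGFR	c.2235_2249del	p.E746_A750del	Exon 19 deletion	indel	EGFR
EGFR	c.2240_2254del	p.L747_T751del	Exon 19 deletion	indel	EGFR
EGFR	c.2240_2257del	p.L747_P753delinsS	Exon 19 deletion	indel	EGFR
EGFR	c.2237_2255delinsT	p.E746_S752delinsV	Exon 19 deletion	indel	EGFR
EGFR	c.2238_2248delinsGC	p.L747_A750delinsP	Exon 19 deletion	indel	EGFR
EGFR	c.2237_2251del	p.E746_T751delinsA	Exon 19 deletion	indel	EGFR
EGFR	c.2239_2256del	p.L747_S752del	Exon 19 deletion	indel	EGFR
EGFR	c.2237_2254del	p.E746_S752delinsA	Exon 19 deletion	indel	EGFR
EGFR	c.2236_2253del	p.E746_T751del	Exon 19 deletion	indel	EGFR
EGFR	c.2239_2247del	p.L747_E749del	Exon 19 deletion	indel	EGFR
EGFR	c.2239_2251delinsC	p.L747_T751delinsP	Exon 19 deletion	indel	EGFR
EGFR	c.2253_2276del	p.S752_I759del	Exon 19 deletion	indel	EGFR
EGFR		p.A767_V769dup	Exon 20 insertion	indel	EGFR
EGFR		p.S768_D770dup	Exon 20 insertion	indel	EGFR
EGFR		p.D770_N771insG	Exon 20 insertion	indel	EGFR
EGFR		p.H773_V774insH	Exon 20 insertion	indel	EGFR
EGFR		p.V769_D770insASV	Exon 20 insertion	indel	EGFR
EGFR		p.N771_P772insH	Exon 20 insertion	indel	EGFR
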