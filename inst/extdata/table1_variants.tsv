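chrom	start	end	ref	alt	aa_change
1	209788553	209788553	G	A	S424L
1	209788556	209788556	A	G	I423T
1	209788568	209788568	A	C	V419G
1	209788614	209788614	C	T	E404K
1	209788625	209788625	C	T	R400Q
1	209788634	209788634	A	G	V397A
1	209788638	209788638	G	A	P396S
1	209789722	209789722	A	G	F375S
1	209790581	209790581	C	T	G325E
1	209790601	209790601	C	A	Q318H
1	209790601	209790601	C	G	Q318H
1	209790674	209790674	A	G	L294P
1	209790735	209790735	C	T	V274I
1	209790783	209790783	G	A	P258S
1	209790799	209790799	G	C	F252L
1	209790799	209790799	G	T	F252L
1	209790801	209790801	A	G	F252L
1	209790806	209790806	C	T	R250Q
1	209792271	209792271	G	A	P222L
1	209792347	209792347	G	A	P197S
1	209796429	209796429	T	C	T100A
1	209796465	209796465	T	G	N88H
1	209796477	209796477	G	A	R84C
1	209796483	209796483	G	T	Q82K
1	209796500	209796500	G	A	P76L
1	209796506	209796506	G	A	P74L
1	209796519	209796519	C	G	G70R
1	209796519	209796519	C	T	G70R
1	209796530	209796530	T	G	K66T
1	209796549	209796549	A	C	W60G
1	209801280	209801280	C	T	R45Q
1	209801281	209801281	G	A	R45W
1	209801313	209801313	T	G	K34T
1	209801379	209801379	G	A	P12L
1	209801388	209801388	C	T	R9Q
1	209801389	209801389	G	A	R9W
1	209801398	209801398	G	A	R6C
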