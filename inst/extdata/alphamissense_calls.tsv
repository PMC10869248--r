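variant_id	aa_change	call
1:209788553:G>A	S424L	PATHOGENIC
1:209788556:A>G	I423T	PATHOGENIC
1:209788568:A>C	V419G	PATHOGENIC
1:209788614:C>T	E404K	PATHOGENIC
1:209788625:C>T	R400Q	BENIGN
1:209788634:A>G	V397A	PATHOGENIC
1:209788638:G>A	P396S	PATHOGENIC
1:209789722:A>G	F375S	PATHOGENIC
1:209790581:C>T	G325E	PATHOGENIC
1:209790601:C>A	Q318H	PATHOGENIC
1:209790601:C>G	Q318H	PATHOGENIC
1:209790674:A>G	L294P	PATHOGENIC
1:209790735:C>T	V274I	BENIGN
1:209790783:G>A	P258S	PATHOGENIC
1:209790799:G>C	F252L	PATHOGENIC
1:209790799:G>T	F252L	PATHOGENIC
1:209790801:A>G	F252L	PATHOGENIC
1:209790806:C>T	R250Q	PATHOGENIC
1:209792271:G>A	P222L	PATHOGENIC
1:209792347:G>A	P197S	BENIGN
1:209796429:T>C	T100A	PATHOGENIC
1:209796465:T>G	N88H	PATHOGENIC
1:209796477:G>A	R84C	PATHOGENIC
1:209796483:G>T	Q82K	PATHOGENIC
1:209796500:G>A	P76L	PATHOGENIC
1:209796506:G>A	P74L	PATHOGENIC
1:209796519:C>G	G70R	PATHOGENIC
1:209796519:C>T	G70R	PATHOGENIC
1:209796530:T>G	K66T	PATHOGENIC
1:209796549:A>C	W60G	PATHOGENIC
1:209801280:C>T	R45Q	PATHOGENIC
1:209801281:G>A	R45W	PATHOGENIC
1:209801313:T>G	K34T	PATHOGENIC
1:209801379:G>A	P12L	PATHOGENIC
1:209801388:C>T	R9Q	PATHOGENIC
1:209801389:G>A	R9W	PATHOGENIC
1:209801398:G>A	R6C	PATHOGENIC
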