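variant_id	aa_change	domain	functional_result	sift	polyphen2	mutationtaster	mutationassessor	intervar	clinvar	block
1:209796477:G>A	R84C	DNA-binding	Ruptured	Yes	Yes	Yes	Yes	Yes	Yes	Agreement
1:209788553:G>A	S424L	C-terminal	Ruptured	Yes	Yes	Yes	VUS	Yes	Yes	Agreement
1:209788638:G>A	P396S	C-terminal	Ruptured	Yes	Yes	Yes	VUS	Yes	Yes	Agreement
1:209796549:A>C	W60G	DNA-binding	Ruptured	Yes	Yes	Yes	Yes	VUS	N/A	Agreement
1:209790735:C>T	V274I	Protein-Binding	Rescued	No	No	Yes	Yes	Yes	Yes	Agreement
1:209790806:C>T	R250Q	Protein-Binding	Ruptured	Yes	Yes	Yes	No	VUS	Yes	Agreement
1:209788614:C>T	E404K	C-terminal	Ruptured	Yes	Yes	Yes	VUS	VUS	Yes	Agreement
1:209796530:T>G	K66T	DNA-binding	Ruptured	Yes	Yes	Yes	VUS	VUS	N/A	Uncertainty
1:209789722:A>G	F375S	Protein-Binding	Ruptured	Yes	Yes	Yes	VUS	VUS	N/A	Uncertainty
1:209790581:C>T	G325E	Protein-Binding	Ruptured	Yes	Yes	Yes	VUS	VUS	N/A	Uncertainty
1:209790601:C>A	Q318H	Protein-Binding	Ruptured	Yes	Yes	Yes	VUS	VUS	N/A	Uncertainty
1:209790601:C>G	Q318H	Protein-Binding	Ruptured	Yes	Yes	Yes	VUS	VUS	N/A	Uncertainty
1:209790674:A>G	L294P	Protein-Binding	Ruptured	Yes	Yes	Yes	VUS	VUS	N/A	Uncertainty
1:209790783:G>A	P258S	Protein-Binding	Ruptured	Yes	Yes	Yes	No	VUS	N/A	Uncertainty
1:209788568:A>C	V419G	C-terminal	Ruptured	Yes	Yes	Yes	VUS	VUS	N/A	Uncertainty
1:209788634:A>G	V397A	C-terminal	Ruptured	Yes	Yes	Yes	No	VUS	N/A	Uncertainty
1:209796429:T>C	T100A	DNA-binding	Rescued	Yes	No	No	Yes	VUS	N/A	Uncertainty
1:209796483:G>T	Q82K	DNA-binding	Rescued	Yes	No	No	Yes	VUS	N/A	Uncertainty
1:209801313:T>G	K34T	DNA-binding	Ruptured	No	Yes	Yes	No	VUS	N/A	Uncertainty
1:209792347:G>A	P197S	Mid-Linker	Rescued	No	Yes	No	Yes	VUS	N/A	Uncertainty
1:209792271:G>A	P222L	Mid-Linker	Rescued	No	No	No	Yes	VUS	VUS	Uncertainty
1:209790799:G>C	F252L	Protein-Binding	Ruptured	No	No	Yes	No	VUS	N/A	Uncertainty
1:209790799:G>T	F252L	Protein-Binding	Ruptured	No	No	Yes	No	VUS	N/A	Uncertainty
1:209790801:A>G	F252L	Protein-Binding	Ruptured	No	No	Yes	No	VUS	N/A	Uncertainty
1:209788625:C>T	R400Q	C-terminal	Rescued	Yes	No	No	VUS	No	No	Uncertainty
1:209801379:G>A	P12L	N-terminal	Rescued	No	No	No	VUS	VUS	N/A	Disagreement
1:209801388:C>T	R9Q	N-terminal	Rescued	No	No	No	VUS	No	No	Disagreement
1:209801389:G>A	R9W	N-terminal	Rescued	No	No	No	No	No	No	Disagreement
1:209801398:G>A	R6C	N-terminal	Rescued	No	No	No	VUS	No	No	Disagreement
1:209796465:T>G	N88H	DNA-binding	Rescued	No	No	No	VUS	VUS	No	Disagreement
1:209796500:G>A	P76L	DNA-binding	Rescued	No	No	No	VUS	VUS	N/A	Disagreement
1:209796506:G>A	P74L	DNA-binding	Rescued	No	No	No	VUS	VUS	N/A	Disagreement
1:209796519:C>G	G70R	DNA-binding	Rescued	No	No	No	VUS	VUS	N/A	Disagreement
1:209796519:C>T	G70R	DNA-binding	Rescued	No	No	No	VUS	VUS	N/A	Disagreement
1:209801280:C>T	R45Q	DNA-binding	Rescued	No	No	No	VUS	VUS	VUS	Disagreement
1:209801281:G>A	R45W	DNA-binding	Rescued	No	No	No	No	VUS	N/A	Disagreement
1:209788556:A>G	I423T	C-terminal	Rescued	No	No	No	VUS	VUS	N/A	Disagreement
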