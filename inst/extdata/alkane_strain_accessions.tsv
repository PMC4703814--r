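strain_id	e_acceptor	affiliation	masd_accession	s16_accession
HxN1	nitrate	Betaproteobacteria	CAO03074	AF331975
OcN1	nitrate	Betaproteobacteria	CBK27727	AF331976
HdN1	nitrate	Gammaproteobacteria	NC_014366	AF331974
BuS5	sulfate	Deltaproteobacteria	AXAM00000002	EF077225
Propane60GuB	sulfate	Firmicutes	LN879422	EF077227
Butane12-Gme	sulfate	Deltaproteobacteria	unpublished	EF077226
PL12	sulfate	Deltaproteobacteria	LC102219	AB468588
ALDC	sulfate	Deltaproteobacteria	GU453656	DQ303457
TD3	sulfate	Deltaproteobacteria	unpublished	X80922
Hxd3	sulfate	Deltaproteobacteria	CP000859.1	AF141881
AK-01	sulfate	Deltaproteobacteria	CP001322.1	NR_074962
PF2803	sulfate	Deltaproteobacteria	LN879420	NR_025795
CV2803	sulfate	Deltaproteobacteria	AUCT01000049	AY184360
LM2801	sulfate	Deltaproteobacteria	LN879421	DQ826724
PnD3	sulfate	Deltaproteobacteria	unpublished	Y17501
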