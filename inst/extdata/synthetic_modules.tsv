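module_id	name	level_B	level_C	definition
MSYN001	Nitrification, synthetic	Energy metabolism	Nitrogen metabolism	K10944+K10945+K10946 K10535
MSYN002	Denitrification, synthetic	Energy metabolism	Nitrogen metabolism	K00368,K15864 K04561+K02305 K00376
MSYN003	Assimilatory nitrate reduction, synthetic	Energy metabolism	Nitrogen metabolism	K00367,K10534 (K00366,K17877)
MSYN004	Reductive citrate cycle, synthetic	Energy metabolism	Carbon fixation	K00169+K00170-K00172 K01007 K00024,K00025
MSYN005	Calvin cycle core, synthetic	Energy metabolism	Carbon fixation	K01601-K01602 K00855 K05298,K00150
MSYN006	Methane oxidation, synthetic	Energy metabolism	Methane metabolism	K10944 K16157,K14028 K00093
MSYN007	Glycolysis core, synthetic	Carbohydrate metabolism	Central carbohydrate metabolism	K00844,K12407 K01810 K00850,K16370 K01623,K01624
MSYN008	Thiamine biosynthesis, synthetic	Metabolism of cofactors and vitamins	Cofactor biosynthesis	K03148 K03149+K03150 K00878,K14153
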