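native_id	name	monoisotopic_mass	kegg_id	pubchem_cid	pubchem_sid	hmdb_ids	inchi	inchi_key
cq_17448	Glycochenodeoxycholic acid 3-glucuronide;(3a,5b,7b)-24-[(carboxymethyl)amino]-7-hydroxy-24-oxocholan-3-yl-b-D-glucopyranosiduronic acid	625.34738				HMDB02618;HMDB02579		ABCDEFGHIJKLMN-BBBBBBBBSA-N
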