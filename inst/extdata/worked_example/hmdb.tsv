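native_id	name	monoisotopic_mass	kegg_id	pubchem_cid	pubchem_sid	hmdb_ids	inchi	inchi_key
HMDB02579	Glycochenodeoxycholic acid 3-glucuronide	625.34738	C03033			HMDB02579		ABCDEFGHIJKLMN-AAAAAAAASA-N
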